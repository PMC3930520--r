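#' Construct a set of functional modules (gene sets)
#'
#' A module is a gene set representing a protein complex or a pathway.
#' Genes may belong to several modules; modules must be non-empty.
#'
#' @param genes Named list of character vectors (module id -> member genes).
#' @param type Character vector, one of `"complex"` or `"pathway"` per
#'   module (recycled).
#' @param label Optional human-readable labels (defaults to the ids).
#'
#' @return An object of class `module_set`: a list with elements `id`,
#'   `genes` (named list), `type`, `label`.
#' @export
module_set <- function(genes, type = "complex", label = NULL) {
  if (!is.list(genes) || is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("'genes' must be a named list of gene vectors", call. = FALSE)
  if (any(lengths(genes) == 0L))
    stop("modules must be non-empty", call. = FALSE)
  n <- length(genes)
  type <- rep_len(as.character(type), n)
  bad <- !type %in% c("complex", "pathway")
  if (any(bad))
    stop("module type must be 'complex' or 'pathway'", call. = FALSE)
  out <- list(
    id = names(genes),
    genes = lapply(genes, as.character),
    type = type,
    label = if (is.null(label)) names(genes) else rep_len(as.character(label), n)
  )
  class(out) <- "module_set"
  out
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (%d complexes, %d pathways), %d distinct genes\n",
              length(x$id), sum(x$type == "complex"), sum(x$type == "pathway"),
              length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$id)

#' Subset a module set to genes present in a given universe
#'
#' Drops genes outside `universe` and then any module left empty.
#'
#' @param modules A `module_set`.
#' @param universe Character vector of genes to keep.
#' @return A `module_set`.
#' @export
restrict_modules <- function(modules, universe) {
  stopifnot(inherits(modules, "module_set"))
  genes <- lapply(modules$genes, function(g) intersect(g, universe))
  keep <- lengths(genes) > 0L
  module_set(genes[keep], type = modules$type[keep], label = modules$label[keep])
}
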