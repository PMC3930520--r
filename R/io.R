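#' @name io
#' @title Plain-text readers and writers
#'
#' @description All intermediate results travel as UTF-8 tab-separated
#' files: `#` lines are comments (every writer emits a provenance header),
#' `NA` marks missing values, and numeric values round-trip to at least
#' 1e-12 relative precision. Malformed rows raise an error naming the file,
#' line and offending field.
NULL

provenance_header <- function(what, extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("giscreen")),
                  error = function(e) "dev")
  c(sprintf("# giscreen %s | %s | written %s", ver, what,
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(extra)) paste0("# ", extra))
}

write_tsv_with_header <- function(df, path, what, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(what, extra), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_checked <- function(path, numeric_cols = character(0),
                             required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  for (cc in intersect(numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad)) {
      stop(sprintf("%s: line %d: field '%s' is not numeric ('%s')",
                   path, bad[1], cc, raw[[cc]][bad[1]]), call. = FALSE)
    }
    raw[[cc]] <- v
  }
  raw
}

#' Write / read plate colony-size tables
#'
#' Long format: plate_id, query, replicate, copy, layout_plate, batch, row,
#' col, size.
#'
#' @param plates Plate data.frame (the `plates` element of a
#'   `screen_plates` or `normalized_plates` object).
#' @param path File path.
#' @rdname io_plates
#' @export
write_plates <- function(plates, path) {
  write_tsv_with_header(plates, path, "plate colony sizes")
}

#' @rdname io_plates
#' @export
read_plates <- function(path) {
  df <- read_tsv_checked(path,
                         numeric_cols = c("replicate", "copy", "layout_plate",
                                          "batch", "row", "col", "size"),
                         required = c("plate_id", "query", "row", "col", "size"))
  for (cc in c("replicate", "copy", "layout_plate", "batch", "row", "col"))
    if (cc %in% names(df)) df[[cc]] <- as.integer(df[[cc]])
  if (any(df$size < 0, na.rm = TRUE))
    stop(path, ": negative colony size", call. = FALSE)
  df
}

#' Write / read strain layouts
#'
#' Columns: layout_plate, row, col, recipient (NA = empty position),
#' dup_group.
#'
#' @param layouts Layout data.frame.
#' @param path File path.
#' @rdname io_layout
#' @export
write_layout <- function(layouts, path) {
  write_tsv_with_header(as.data.frame(layouts), path, "strain layout")
}

#' @rdname io_layout
#' @export
read_layout <- function(path) {
  df <- read_tsv_checked(path,
                         numeric_cols = c("layout_plate", "row", "col", "dup_group"),
                         required = c("layout_plate", "row", "col", "recipient"))
  for (cc in c("layout_plate", "row", "col", "dup_group"))
    if (cc %in% names(df)) df[[cc]] <- as.integer(df[[cc]])
  class(df) <- c("strain_layout", "data.frame")
  df
}

#' Write / read an S-score matrix
#'
#' The S matrix is written genes-as-headers (first column `query`), masked
#' cells as `NA`; the mask matrix travels in a companion file so that
#' reading restores the full object (S, mask, n_obs).
#'
#' @param sm A `score_matrix`.
#' @param path Path for the S matrix TSV.
#' @param mask_path,n_obs_path Companion paths (defaults: path with
#'   `_mask` / `_nobs` suffixed before the extension).
#' @rdname io_score_matrix
#' @export
write_score_matrix <- function(sm, path,
                               mask_path = companion_path(path, "mask"),
                               n_obs_path = companion_path(path, "nobs")) {
  stopifnot(inherits(sm, "score_matrix"))
  S <- sm$S
  S[sm$mask != "ok"] <- NA_real_
  write_named_matrix(S, path, "S-score matrix", numeric = TRUE)
  write_named_matrix(sm$mask, mask_path, "S-score mask", numeric = FALSE)
  write_named_matrix(sm$n_obs, n_obs_path, "observations per pair",
                     numeric = TRUE)
  invisible(path)
}

companion_path <- function(path, tag) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  paste0(base, "_", tag, if (nzchar(ext)) paste0(".", ext) else "")
}

write_named_matrix <- function(m, path, what, numeric = TRUE) {
  df <- data.frame(query = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  vals <- as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, vals)
  write_tsv_with_header(df, path, what)
}

read_named_matrix <- function(path, numeric = TRUE) {
  df <- read_tsv_checked(path, required = "query")
  rn <- df$query
  m <- as.matrix(df[, setdiff(names(df), "query"), drop = FALSE])
  rownames(m) <- rn
  if (numeric) {
    mm <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    bad <- which(is.na(mm) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("%s: line %d: field '%s' is not numeric", path,
                   bad[1, 1], colnames(m)[bad[1, 2]]), call. = FALSE)
    m <- mm
  }
  m
}

#' @rdname io_score_matrix
#' @export
read_score_matrix <- function(path,
                              mask_path = companion_path(path, "mask"),
                              n_obs_path = companion_path(path, "nobs")) {
  S <- read_named_matrix(path, numeric = TRUE)
  mask <- if (file.exists(mask_path)) {
    read_named_matrix(mask_path, numeric = FALSE)
  } else {
    ifelse(is.na(S), "missing", "ok")
  }
  n_obs <- if (file.exists(n_obs_path)) {
    nm <- read_named_matrix(n_obs_path, numeric = TRUE)
    storage.mode(nm) <- "integer"
    nm
  } else {
    matrix(NA_integer_, nrow(S), ncol(S), dimnames = dimnames(S))
  }
  ok <- mask == "ok"
  Z <- S
  if (sum(ok, na.rm = TRUE) > 1)
    Z[ok] <- (S[ok] - mean(S[ok], na.rm = TRUE)) / stats::sd(S[ok], na.rm = TRUE)
  out <- list(S = S, Z = Z, n_obs = n_obs, mask = mask,
              queries = rownames(S), recipients = colnames(S),
              variance_floor = NA_real_, scale = NA_real_, fitness = NULL)
  class(out) <- "score_matrix"
  out
}

#' Write / read a signed edge list
#'
#' Four columns: gene_a, gene_b, S, sign. The node universe (screened
#' genes) is carried on a `# nodes:` comment line so permutation nulls can
#' be reproduced from the file alone.
#'
#' @param net A `gi_network`.
#' @param path File path.
#' @rdname io_edges
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gi_network"))
  write_tsv_with_header(net$edges, path, "signed GI edge list",
                        extra = paste("nodes:", paste(net$nodes, collapse = ",")))
}

#' @rdname io_edges
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  node_line <- grep("^# nodes:", lines, value = TRUE)
  df <- read_tsv_checked(path, numeric_cols = "S",
                         required = c("gene_a", "gene_b", "S", "sign"))
  nodes <- if (length(node_line)) {
    strsplit(sub("^# nodes:\\s*", "", node_line[1]), ",", fixed = TRUE)[[1]]
  } else {
    NULL
  }
  gi_network(df, nodes = nodes)
}

#' Write / read gene-set (GMT-style) module files
#'
#' One module per line: id, `type|label`, then tab-separated member genes.
#'
#' @param modules A `module_set`.
#' @param path File path.
#' @rdname io_gmt
#' @export
write_gmt <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(modules$id)) {
    writeLines(paste(c(modules$id[i],
                       paste0(modules$type[i], "|", modules$label[i]),
                       modules$genes[[i]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname io_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d: GMT rows need id, description and >= 1 gene",
                 path, bad[1]), call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- strsplit(vapply(parts, `[[`, "", 2L), "|", fixed = TRUE)
  type <- vapply(desc, `[[`, "", 1L)
  label <- vapply(desc, function(d) if (length(d) > 1) d[[2]] else d[[1]], "")
  genes <- lapply(parts, function(p) p[-(1:2)])
  names(genes) <- ids
  module_set(genes, type = type, label = label)
}

#' Write / read per-gene annotation tables
#'
#' Columns: gene, fitness, class (deletion/hypomorph), coordinate,
#' operon_id, operon_pos, module_id, process (`|`-separated for
#' multi-label).
#'
#' @param annotations Data.frame (e.g. `truth$genes`).
#' @param path File path.
#' @rdname io_annotations
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_with_header(annotations, path, "gene annotations")
}

#' @rdname io_annotations
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path,
                         numeric_cols = c("fitness", "coordinate", "operon_pos"),
                         required = "gene")
  if ("operon_pos" %in% names(df)) df$operon_pos <- as.integer(df$operon_pos)
  if ("coordinate" %in% names(df)) df$coordinate <- as.numeric(df$coordinate)
  df
}

#' Write / read planted-interaction (ground truth epsilon) tables
#'
#' @param epsilon Data.frame with query, recipient, epsilon.
#' @param path File path.
#' @rdname io_epsilon
#' @export
write_epsilon <- function(epsilon, path) {
  write_tsv_with_header(epsilon, path, "planted epistasis deviations")
}

#' @rdname io_epsilon
#' @export
read_epsilon <- function(path) {
  read_tsv_checked(path, numeric_cols = "epsilon",
                   required = c("query", "recipient", "epsilon"))
}

#' Write / read phylogenetic profile matrices
#'
#' Genes x genomes 0/1 table; genome column headers carry the group label
#' as `genome|group`.
#'
#' @param profiles A `phylo_profiles` object.
#' @param path File path.
#' @rdname io_profiles
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "phylo_profiles"))
  m <- profiles$presence
  colnames(m) <- paste0(profiles$genomes, "|", profiles$genome_group)
  write_named_matrix(m, path, "phylogenetic profiles")
}

#' @rdname io_profiles
#' @export
read_profiles <- function(path) {
  m <- read_named_matrix(path, numeric = TRUE)
  if (any(!m %in% c(0, 1)))
    stop(path, ": profile entries must be 0/1", call. = FALSE)
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s: column '%s' lacks a genome|group header", path,
                 colnames(m)[bad[1]]), call. = FALSE)
  genomes <- vapply(parts, `[[`, "", 1L)
  groups <- vapply(parts, `[[`, "", 2L)
  colnames(m) <- genomes
  storage.mode(m) <- "integer"
  out <- list(presence = m, genome_group = groups, genomes = genomes)
  class(out) <- "phylo_profiles"
  out
}

#' Check a network against published summary counts
#'
#' Compares computed network statistics with a two-column table of expected
#' values (`metric`, `value`) such as one derived from a publication's
#' supplementary tables. Supported metrics: `n_aggravating`,
#' `n_alleviating`, `acc`, `n_hubs` (at `hub_min_degree`). Returns `NULL`
#' invisibly, with a message, when the expectation file is absent.
#'
#' @param net A `gi_network`.
#' @param expected_path Path to the expectation TSV.
#' @param hub_min_degree Hub threshold used for `n_hubs` (default 640).
#' @param tolerance Relative tolerance for real-valued metrics
#'   (default 0.05).
#' @return Data.frame: metric, expected, observed, ok — or `NULL` when the
#'   file is missing.
#' @export
check_published_counts <- function(net, expected_path, hub_min_degree = 640,
                                   tolerance = 0.05) {
  stopifnot(inherits(net, "gi_network"))
  if (!file.exists(expected_path)) {
    message("expected-count table not available: ", expected_path,
            "; skipping published-count comparison")
    return(invisible(NULL))
  }
  exp_df <- read_tsv_checked(expected_path, numeric_cols = "value",
                             required = c("metric", "value"))
  topo <- gi_topology(net, hub_min_degree = hub_min_degree)
  observed <- c(
    n_aggravating = sum(net$edges$sign == "aggravating"),
    n_alleviating = sum(net$edges$sign == "alleviating"),
    acc = topo$acc,
    n_hubs = length(topo$hubs)
  )
  unknown <- setdiff(exp_df$metric, names(observed))
  if (length(unknown))
    stop("unknown metric(s) in expectation table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  obs <- observed[exp_df$metric]
  integerish <- exp_df$metric %in% c("n_aggravating", "n_alleviating", "n_hubs")
  ok <- ifelse(integerish, obs == exp_df$value,
               abs(obs - exp_df$value) <= tolerance * pmax(abs(exp_df$value), 1e-12))
  data.frame(metric = exp_df$metric, expected = exp_df$value,
             observed = unname(obs), ok = ok, stringsAsFactors = FALSE)
}

#' Write a ground truth as TSV sidecars
#'
#' Writes the gene annotation table, the planted-interaction table and the
#' module GMT next to each other so tests and downstream stages can assert
#' against the truth from disk.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(truth$genes, file.path(dir, "genes.tsv"))
  write_epsilon(truth$epsilon, file.path(dir, "epsilon.tsv"))
  if (!is.null(truth$modules)) write_gmt(truth$modules, file.path(dir, "modules.gmt"))
  invisible(dir)
}
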