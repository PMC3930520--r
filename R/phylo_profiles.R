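#' Generate synthetic phylogenetic profiles with planted co-retention
#'
#' Builds a binary gene x genome presence/absence matrix over three genome
#' groups emulating an ortholog survey across a bacterial class: closely
#' related serotypes of the screened species, the surrounding
#' enterobacteria, and the wider gamma-proteobacteria (defaults 29/64/140 =
#' 233 genomes). Each planted module carries a latent retention pattern;
#' member genes copy it with probability `co_retention` and otherwise draw
#' independently, so genes of the same module share a correlated presence
#' pattern. Retention decays with phylogenetic distance via group exponents:
#' the per-genome presence probability in group g is `retention^alpha_g`
#' (alpha = 0.25 / 1 / 2 for serotypes / enterobacteria / gamma), so
#' `retention = 1` yields an all-present matrix.
#'
#' @param truth A [generate_ground_truth()] result (module membership is
#'   taken from it).
#' @param n_genomes_per_group Named/ordered counts for the three groups
#'   (default `c(serotype = 29, enterobacteria = 64, gamma = 140)`).
#' @param retention Per-module baseline retention probability in `[0, 1]`
#'   (recycled over modules; default 0.75). Genes outside modules use
#'   `background_retention`.
#' @param background_retention Baseline retention of unmoduled genes
#'   (default 0.5).
#' @param co_retention Probability that a module gene copies its module's
#'   latent pattern in a genome (default 0.9).
#' @param group_alpha Exponents tilting retention by group (default
#'   `c(0.25, 1, 2)`).
#' @param rng_seed Seed for the draw.
#' @return Object of class `phylo_profiles`: list with `presence` (gene x
#'   genome 0/1 matrix), `genome_group` (per-column labels), `genomes`.
#' @export
generate_phylo_profiles <- function(truth,
                                    n_genomes_per_group = c(serotype = 29,
                                                            enterobacteria = 64,
                                                            gamma = 140),
                                    retention = 0.75,
                                    background_retention = 0.5,
                                    co_retention = 0.9,
                                    group_alpha = c(0.25, 1, 2),
                                    rng_seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(n_genomes_per_group) != 3L || any(n_genomes_per_group < 1))
    stop("invalid configuration: n_genomes_per_group must be three positive counts",
         call. = FALSE)
  if (any(retention < 0 | retention > 1) ||
      background_retention < 0 || background_retention > 1 ||
      co_retention < 0 || co_retention > 1)
    stop("invalid configuration: retention probabilities must lie in [0, 1]",
         call. = FALSE)
  set.seed(rng_seed)
  groups <- names(n_genomes_per_group)
  if (is.null(groups)) groups <- c("serotype", "enterobacteria", "gamma")
  genome_group <- rep(groups, times = n_genomes_per_group)
  n_genomes <- length(genome_group)
  genomes <- sprintf("%s_%03d", genome_group, unlist(lapply(n_genomes_per_group, seq_len)))
  genes <- truth$genes$gene
  module_of <- stats::setNames(truth$genes$module_id, genes)
  mod_ids <- if (is.null(truth$modules)) character(0) else truth$modules$id
  retention <- rep_len(retention, max(1L, length(mod_ids)))
  names(retention) <- if (length(mod_ids)) mod_ids else NULL
  alpha <- rep(group_alpha, times = n_genomes_per_group)

  p_of <- function(base) base^alpha   # per-genome presence probability
  X <- matrix(0L, length(genes), n_genomes, dimnames = list(genes, genomes))
  ## latent module patterns
  latent <- lapply(mod_ids, function(m) {
    as.integer(stats::runif(n_genomes) < p_of(retention[[m]]))
  })
  names(latent) <- mod_ids
  for (i in seq_along(genes)) {
    m <- module_of[[i]]
    if (!is.na(m) && m %in% mod_ids) {
      p <- p_of(retention[[m]])
      copy <- stats::runif(n_genomes) < co_retention
      own <- as.integer(stats::runif(n_genomes) < p)
      X[i, ] <- ifelse(copy, latent[[m]], own)
    } else {
      X[i, ] <- as.integer(stats::runif(n_genomes) < p_of(background_retention))
    }
  }
  out <- list(presence = X, genome_group = genome_group, genomes = genomes)
  class(out) <- "phylo_profiles"
  out
}

#' @export
print.phylo_profiles <- function(x, ...) {
  tab <- table(x$genome_group)
  cat(sprintf("phylo_profiles: %d genes x %d genomes (%s)\n",
              nrow(x$presence), ncol(x$presence),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
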