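#' Mutual information between two binary phylogenetic profiles
#'
#' Plug-in (maximum-likelihood) estimator in bits:
#' `MI = sum over x,y of p(x,y) log2(p(x,y) / (p(x) p(y)))`, with empty
#' joint cells contributing 0. A constant profile carries no information
#' (MI = 0). Optionally normalized by the joint entropy.
#'
#' @param profile_a,profile_b Equal-length 0/1 vectors (length >= 2).
#' @param normalized Divide by the joint entropy (default FALSE: raw bits).
#' @return MI in bits (or the normalized value).
#' @export
mutual_information <- function(profile_a, profile_b, normalized = FALSE) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length", call. = FALSE)
  if (length(profile_a) < 2L)
    stop("profiles must have length >= 2", call. = FALSE)
  a <- as.integer(profile_a); b <- as.integer(profile_b)
  if (any(is.na(a)) || any(is.na(b)) || any(a > 1L | a < 0L | b > 1L | b < 0L))
    stop("profiles must be binary (0/1)", call. = FALSE)
  n <- length(a)
  joint <- matrix(0, 2, 2)
  joint[1, 1] <- sum(a == 0 & b == 0); joint[1, 2] <- sum(a == 0 & b == 1)
  joint[2, 1] <- sum(a == 1 & b == 0); joint[2, 2] <- sum(a == 1 & b == 1)
  pj <- joint / n
  pa <- rowSums(pj); pb <- colSums(pj)
  mi <- 0; hj <- 0
  for (x in 1:2) for (y in 1:2) {
    if (pj[x, y] > 0) {
      mi <- mi + pj[x, y] * log2(pj[x, y] / (pa[x] * pb[y]))
      hj <- hj - pj[x, y] * log2(pj[x, y])
    }
  }
  mi <- max(0, mi)   # clip tiny negative rounding
  if (normalized) {
    if (hj == 0) return(0)
    mi / hj
  } else {
    mi
  }
}

#' Pairwise mutual information over a profile matrix
#'
#' @param profiles A `phylo_profiles` object or a gene x genome 0/1 matrix.
#' @param normalized See [mutual_information()].
#' @return Symmetric gene x gene MI matrix (bits).
#' @export
profile_mi <- function(profiles, normalized = FALSE) {
  X <- profile_matrix(profiles)
  n <- ncol(X)
  n11 <- tcrossprod(X)
  rs <- rowSums(X)
  n10 <- outer(rs, rs, function(a, b) a) - n11
  n01 <- outer(rs, rs, function(a, b) b) - n11
  n00 <- n - n11 - n10 - n01
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  term <- function(nxy, px, py) {
    p <- nxy / n
    ifelse(p > 0, p * (log2(p) - log2(px) - log2(py)), 0)
  }
  p1a <- rs / n; p0a <- 1 - p1a
  P1 <- outer(p1a, p1a, function(a, b) a); Q1 <- outer(p1a, p1a, function(a, b) b)
  mi <- term(n00, 1 - P1, 1 - Q1) + term(n01, 1 - P1, Q1) +
    term(n10, P1, 1 - Q1) + term(n11, P1, Q1)
  mi[mi < 0] <- 0
  if (normalized) {
    hj <- -(plogp(n00 / n) + plogp(n01 / n) + plogp(n10 / n) + plogp(n11 / n))
    mi <- ifelse(hj > 0, mi / hj, 0)
  }
  dimnames(mi) <- list(rownames(X), rownames(X))
  mi
}

profile_matrix <- function(profiles) {
  if (inherits(profiles, "phylo_profiles")) profiles$presence else {
    stopifnot(is.matrix(profiles))
    profiles
  }
}

#' Select an MI cutoff by precision-recall against a gold standard
#'
#' Same contract as [pr_cutoff()] applied to pairwise MI scores: sweep a
#' cutoff grid, compute precision and recall on gold-standard positive and
#' negative pairs, pick the smallest cutoff reaching the precision target.
#'
#' @param mi Symmetric MI matrix (e.g. [profile_mi()]).
#' @param gold List with `positive` / `negative` pair data.frames.
#' @param cutoffs Cutoff grid (default `seq(0, 1, by = 0.05)`).
#' @param precision_target Default 0.8.
#' @return A `pr_curve` (see [pr_cutoff()]).
#' @export
mi_cutoff_pr <- function(mi, gold, cutoffs = seq(0, 1, by = 0.05),
                         precision_target = 0.8) {
  stopifnot(is.matrix(mi))
  idx <- which(upper.tri(mi), arr.ind = TRUE)
  scores <- data.frame(gene_a = rownames(mi)[idx[, 1]],
                       gene_b = colnames(mi)[idx[, 2]],
                       score = mi[idx], stringsAsFactors = FALSE)
  pr_cutoff(scores, gold, cutoffs = cutoffs, precision_target = precision_target)
}

#' Co-conserved, correlated gene clusters
#'
#' Builds a graph on the gene pairs that are both highly correlated in
#' their GI profiles (`r >= pcc_min`) and co-conserved (`MI >= mi_min`),
#' reports its connected components as clusters (with maximal cliques
#' enumerated inside components of at most `max_clique_component` genes),
#' and flags co-conserved but anti-correlated pairs (`r <= anti_max`).
#'
#' @param pairs Data.frame with gene_a, gene_b, r, mi.
#' @param pcc_min,mi_min,anti_max Thresholds (defaults 0.5, 0.2, -0.5).
#' @param max_clique_component Maximum component size for clique listing
#'   (default 25).
#' @return List of class `coconserved_clusters`: `clusters` (data.frame:
#'   cluster, n_genes, genes, mean_mi, mean_r), `cliques` (list of gene
#'   vectors), `anti_correlated` (data.frame subset of `pairs`).
#' @export
coconserved_clusters <- function(pairs, pcc_min = 0.5, mi_min = 0.2,
                                 anti_max = -0.5, max_clique_component = 25) {
  stopifnot(all(c("gene_a", "gene_b", "r", "mi") %in% names(pairs)))
  pass <- !is.na(pairs$r) & !is.na(pairs$mi) &
    pairs$r >= pcc_min & pairs$mi >= mi_min
  anti <- !is.na(pairs$r) & !is.na(pairs$mi) &
    pairs$r <= anti_max & pairs$mi >= mi_min
  anti_df <- pairs[anti, , drop = FALSE]
  if (!any(pass)) {
    return(structure(list(
      clusters = data.frame(cluster = integer(0), n_genes = integer(0),
                            genes = character(0), mean_mi = numeric(0),
                            mean_r = numeric(0)),
      cliques = list(), anti_correlated = anti_df),
      class = "coconserved_clusters"))
  }
  sub <- pairs[pass, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  clusters <- lapply(seq_len(comp$no), function(k) {
    genes <- names(comp$membership)[comp$membership == k]
    inside <- sub$gene_a %in% genes & sub$gene_b %in% genes
    data.frame(cluster = k, n_genes = length(genes),
               genes = paste(sort(genes), collapse = ";"),
               mean_mi = mean(sub$mi[inside]),
               mean_r = mean(sub$r[inside]),
               stringsAsFactors = FALSE)
  })
  cliques <- list()
  for (k in seq_len(comp$no)) {
    genes <- names(comp$membership)[comp$membership == k]
    if (length(genes) < 3 || length(genes) > max_clique_component) next
    sg <- igraph::induced_subgraph(g, genes)
    cl <- igraph::max_cliques(sg, min = 3)
    cliques <- c(cliques, lapply(cl, function(v) sort(names(v))))
  }
  structure(list(clusters = do.call(rbind, clusters), cliques = cliques,
                 anti_correlated = anti_df),
            class = "coconserved_clusters")
}

#' @export
print.coconserved_clusters <- function(x, ...) {
  cat(sprintf("coconserved_clusters: %d clusters, %d cliques (>=3), %d anti-correlated pairs\n",
              nrow(x$clusters), length(x$cliques), nrow(x$anti_correlated)))
  invisible(x)
}

#' Fraction of a genome group in which genes are conserved
#'
#' @param profiles A `phylo_profiles` object.
#' @param genes Genes to report (default all).
#' @param group Genome group label (one of the profile's groups).
#' @return List with `per_gene` (named fractions) and `mean` (set mean).
#' @export
conservation_fraction <- function(profiles, genes = NULL, group) {
  stopifnot(inherits(profiles, "phylo_profiles"))
  if (!group %in% unique(profiles$genome_group))
    stop("unknown genome group: ", group, call. = FALSE)
  cols <- profiles$genome_group == group
  X <- profiles$presence[, cols, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing))
      stop("genes absent from profiles: ", paste(missing, collapse = ", "),
           call. = FALSE)
    X <- X[genes, , drop = FALSE]
  }
  per_gene <- rowMeans(X)
  list(per_gene = per_gene, mean = mean(per_gene))
}
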