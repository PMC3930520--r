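# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths (and where possible the library
# calls) they are checking.

# two-sided Fisher p for a 2x2 table by full enumeration over the
# hypergeometric support, probabilities from log-binomial coefficients
fisher_enum_p <- function(tab) {
  m <- rowSums(tab); n <- colSums(tab); N <- sum(tab)
  lo <- max(0, n[1] - m[2]); hi <- min(m[1], n[1])
  ks <- lo:hi
  logp <- lchoose(m[1], ks) + lchoose(m[2], n[1] - ks) - lchoose(N, n[1])
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[ks == tab[1, 1]]
  sum(p[p <= obs * (1 + 1e-7)])
}

# hypergeometric upper tail P(X >= k) by explicit summation
hyper_tail_enum <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# two-sample KS statistic by sweeping every jump point of both ECDFs
ks_D_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), 0)
  Fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(Fx - Fy))
}

# plug-in mutual information from an explicit 2x2 joint count table
mi_from_counts <- function(n00, n01, n10, n11) {
  n <- n00 + n01 + n10 + n11
  pj <- c(n00, n01, n10, n11) / n
  pa <- c(pj[1] + pj[2], pj[3] + pj[4])
  pb <- c(pj[1] + pj[3], pj[2] + pj[4])
  marg <- c(pa[1] * pb[1], pa[1] * pb[2], pa[2] * pb[1], pa[2] * pb[2])
  sum(ifelse(pj > 0, pj * log2(pj / marg), 0))
}

# brute-force recount of signed edges between two gene sets under the
# shared-gene exclusion rule
recount_inter <- function(edges, set_a, set_b) {
  ea <- setdiff(set_a, set_b); eb <- setdiff(set_b, set_a)
  agg <- 0L; all_ <- 0L
  for (i in seq_len(nrow(edges))) {
    ga <- edges$gene_a[i]; gb <- edges$gene_b[i]
    span <- (ga %in% ea && gb %in% eb) || (ga %in% eb && gb %in% ea)
    if (span) {
      if (edges$sign[i] == "aggravating") agg <- agg + 1L else all_ <- all_ + 1L
    }
  }
  c(aggravating = agg, alleviating = all_)
}

recount_intra <- function(edges, set_a) {
  agg <- 0L; all_ <- 0L
  for (i in seq_len(nrow(edges))) {
    if (edges$gene_a[i] %in% set_a && edges$gene_b[i] %in% set_a) {
      if (edges$sign[i] == "aggravating") agg <- agg + 1L else all_ <- all_ + 1L
    }
  }
  c(aggravating = agg, alleviating = all_)
}

# fabricate a score_matrix object directly (for threshold/mask tests)
fake_score_matrix <- function(S, mask = NULL, n_obs = NULL) {
  if (is.null(mask)) mask <- matrix("ok", nrow(S), ncol(S), dimnames = dimnames(S))
  if (is.null(n_obs)) n_obs <- matrix(4L, nrow(S), ncol(S), dimnames = dimnames(S))
  structure(list(S = S, Z = S, n_obs = n_obs, mask = mask,
                 queries = rownames(S), recipients = colnames(S),
                 variance_floor = 1, scale = 1, fitness = NULL),
            class = "score_matrix")
}

# fabricate a profile_correlation object from a full correlation matrix
fake_profile_correlation <- function(r, min_overlap = 1) {
  structure(list(r = r, n = matrix(100L, nrow(r), ncol(r), dimnames = dimnames(r)),
                 genes = rownames(r), min_overlap = min_overlap),
            class = "profile_correlation")
}
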