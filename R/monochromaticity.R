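#' Monochromatic score of a gene-group pair
#'
#' Sign purity of the interactions between two gene groups, anchored at -1
#' when every interaction is aggravating and +1 when every interaction is
#' alleviating:
#' `M = (n_alleviating - n_aggravating) / (n_alleviating + n_aggravating)`.
#'
#' @param n_aggravating,n_alleviating Non-negative interaction counts
#'   (vectorized).
#' @return M in `[-1, 1]`; an error if both counts are zero.
#' @export
monochromatic_score <- function(n_aggravating, n_alleviating) {
  if (any(n_aggravating < 0) || any(n_alleviating < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- n_aggravating + n_alleviating
  if (any(tot == 0))
    stop("monochromatic score undefined when both counts are zero",
         call. = FALSE)
  (n_alleviating - n_aggravating) / tot
}

#' Signed interaction counts between bioprocess categories
#'
#' For every unordered pair of process labels (including self pairs), counts
#' the aggravating and alleviating network edges with one endpoint carrying
#' each label. Genes may carry several labels and then contribute once to
#' every label pair they span; unannotated genes are ignored.
#'
#' @param net A `gi_network`.
#' @param annotations Either a data.frame with `gene` and `process`
#'   (`|`-separated for multi-label genes) or a named list gene -> label
#'   vector.
#' @return Data.frame of class `process_pair_counts`: process_a, process_b
#'   (process_a <= process_b), n_aggravating, n_alleviating, and M where
#'   defined.
#' @export
process_pair_counts <- function(net, annotations) {
  stopifnot(inherits(net, "gi_network"))
  labs <- process_labels(annotations)
  ed <- net$edges
  acc <- new.env(parent = emptyenv())
  add <- function(pa, pb, agg) {
    key <- paste(pa, pb, sep = "\r")
    cur <- if (is.null(acc[[key]])) c(0L, 0L) else acc[[key]]
    acc[[key]] <- cur + if (agg) c(1L, 0L) else c(0L, 1L)
  }
  for (i in seq_len(nrow(ed))) {
    la <- labs[[ed$gene_a[i]]]
    lb <- labs[[ed$gene_b[i]]]
    if (is.null(la) || is.null(lb) || !length(la) || !length(lb)) next
    combos <- unique(t(apply(expand.grid(a = la, b = lb, stringsAsFactors = FALSE),
                             1, function(x) sort(c(x[["a"]], x[["b"]])))))
    agg <- ed$sign[i] == "aggravating"
    for (j in seq_len(nrow(combos))) add(combos[j, 1], combos[j, 2], agg)
  }
  keys <- ls(acc)
  if (length(keys) == 0L) {
    out <- data.frame(process_a = character(0), process_b = character(0),
                      n_aggravating = integer(0), n_alleviating = integer(0),
                      M = numeric(0), stringsAsFactors = FALSE)
  } else {
    parts <- matrix(unlist(strsplit(keys, "\r", fixed = TRUE)), ncol = 2, byrow = TRUE)
    cnt <- t(vapply(keys, function(k) acc[[k]], integer(2)))
    out <- data.frame(process_a = parts[, 1], process_b = parts[, 2],
                      n_aggravating = cnt[, 1], n_alleviating = cnt[, 2],
                      stringsAsFactors = FALSE)
    out$M <- monochromatic_score(out$n_aggravating, out$n_alleviating)
    out <- out[order(out$process_a, out$process_b), ]
    rownames(out) <- NULL
  }
  class(out) <- c("process_pair_counts", "data.frame")
  out
}

process_labels <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "process") %in% names(annotations)))
    labs <- strsplit(ifelse(is.na(annotations$process), "", annotations$process),
                     "|", fixed = TRUE)
    names(labs) <- annotations$gene
    labs
  } else if (is.list(annotations)) {
    annotations
  } else {
    stop("annotations must be a data.frame or named list", call. = FALSE)
  }
}

#' Enrichment of interactions between process categories
#'
#' Hypergeometric upper-tail p for each process pair's interaction count:
#' the urn holds every unordered pair of annotated tested genes, successes
#' are the pairs spanning the two categories, and draws are the network's
#' edges among annotated genes. A label-permutation p (shuffling gene
#' labels, preserving the label multiset) is available as an alternative.
#' Both the per-pair (any sign) and per-sign p-values are reported;
#' Benjamini-Hochberg q-values are added across pairs.
#'
#' @param counts A [process_pair_counts()] result.
#' @param net The `gi_network` the counts came from.
#' @param annotations As in [process_pair_counts()].
#' @param method `"hypergeometric"` (default) or `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param rng_seed Optional seed.
#' @return The counts data.frame with columns `p` (any sign),
#'   `p_aggravating`, `p_alleviating`, `q` added. Categories with fewer than
#'   2 tested genes are skipped (NA p).
#' @export
pair_enrichment <- function(counts, net, annotations,
                            method = c("hypergeometric", "permutation"),
                            n_perm = 1000, rng_seed = NULL) {
  method <- match.arg(method)
  labs <- process_labels(annotations)
  labs <- labs[intersect(names(labs), net$nodes)]
  nlab <- lengths(labs)
  genes <- names(labs)[nlab > 0]
  labs <- labs[genes]
  size <- table(unlist(labs))
  ed <- net$edges
  ed <- ed[ed$gene_a %in% genes & ed$gene_b %in% genes, ]
  n_edges <- nrow(ed)
  n_genes <- length(genes)
  N_pairs <- choose(n_genes, 2)

  pair_capacity <- function(a, b) {
    sa <- if (a %in% names(size)) size[[a]] else 0L
    sb <- if (b %in% names(size)) size[[b]] else 0L
    if (sa < 2L && a == b) return(NA_real_)
    if (a == b) return(choose(sa, 2))
    if (sa < 1L || sb < 1L) return(0)
    shared <- sum(vapply(labs, function(l) all(c(a, b) %in% l), logical(1)))
    sa * sb - shared - choose(shared, 2)
  }

  hyper_p <- function(k, K) {
    if (is.na(K) || K <= 0) return(1)
    stats::phyper(k - 1, K, N_pairs - K, n_edges, lower.tail = FALSE)
  }

  ka <- counts$n_aggravating; kv <- counts$n_alleviating
  Kcap <- mapply(pair_capacity, counts$process_a, counts$process_b)
  skipped <- is.na(Kcap)
  if (method == "hypergeometric") {
    counts$p <- mapply(function(k, K) hyper_p(k, K), ka + kv, Kcap)
    n_agg_tot <- sum(ed$sign == "aggravating")
    n_all_tot <- n_edges - n_agg_tot
    counts$p_aggravating <- mapply(function(k, K) {
      if (is.na(K) || K <= 0) return(1)
      stats::phyper(k - 1, K, N_pairs - K, n_agg_tot, lower.tail = FALSE)
    }, ka, Kcap)
    counts$p_alleviating <- mapply(function(k, K) {
      if (is.na(K) || K <= 0) return(1)
      stats::phyper(k - 1, K, N_pairs - K, n_all_tot, lower.tail = FALSE)
    }, kv, Kcap)
  } else {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    obs_tot <- ka + kv
    exceed <- exceed_a <- exceed_v <- rep(0L, nrow(counts))
    key <- paste(counts$process_a, counts$process_b, sep = "\r")
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(labs[sample.int(length(labs))], names(labs))
      pc <- process_pair_counts(net, perm)
      pk <- paste(pc$process_a, pc$process_b, sep = "\r")
      tot_b <- agg_b <- all_b <- rep(0L, nrow(counts))
      m <- match(key, pk)
      hit <- !is.na(m)
      tot_b[hit] <- pc$n_aggravating[m[hit]] + pc$n_alleviating[m[hit]]
      agg_b[hit] <- pc$n_aggravating[m[hit]]
      all_b[hit] <- pc$n_alleviating[m[hit]]
      exceed <- exceed + (tot_b >= obs_tot)
      exceed_a <- exceed_a + (agg_b >= ka)
      exceed_v <- exceed_v + (all_b >= kv)
    }
    counts$p <- (1 + exceed) / (1 + n_perm)
    counts$p_aggravating <- (1 + exceed_a) / (1 + n_perm)
    counts$p_alleviating <- (1 + exceed_v) / (1 + n_perm)
  }
  counts$p[skipped] <- NA_real_
  counts$q <- stats::p.adjust(counts$p, method = "BH")
  counts
}
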