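#' Pairwise correlation of genetic-interaction profiles
#'
#' A gene's GI profile is its vector of S-scores across all partners.
#' Correlations are computed between recipient rows over the queries where
#' both cells are unmasked (pairwise-complete); pairs with fewer than
#' `min_overlap` shared queries, or with a constant profile, are undefined
#' (`NA`). Query-axis profiles are available via `axis = "query"`.
#'
#' @param sm A `score_matrix`.
#' @param min_overlap Minimum shared unmasked cells per pair (default 20).
#' @param axis `"recipient"` (default: profiles over queries) or `"query"`.
#' @return An object of class `profile_correlation`: list with `r`
#'   (symmetric correlation matrix, diagonal 1 where defined), `n`
#'   (overlap counts), `genes`, `min_overlap`.
#' @export
profile_pcc <- function(sm, min_overlap = 20, axis = c("recipient", "query")) {
  stopifnot(inherits(sm, "score_matrix"))
  axis <- match.arg(axis)
  X <- sm$S
  X[sm$mask != "ok"] <- NA_real_
  if (axis == "recipient") X <- X else X <- t(X)   # columns = profiled genes
  if (nrow(X) < 2L) stop("need at least 2 profile positions", call. = FALSE)
  n <- crossprod(!is.na(X))
  suppressWarnings(r <- stats::cor(X, use = "pairwise.complete.obs"))
  r[n < min_overlap] <- NA_real_
  out <- list(r = r, n = n, genes = colnames(X), min_overlap = min_overlap)
  class(out) <- "profile_correlation"
  out
}

#' @export
print.profile_correlation <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("profile_correlation: %d genes, %d defined pairs (min_overlap %d)\n",
              length(x$genes), sum(!is.na(off)), x$min_overlap))
  invisible(x)
}

## r values for a two-column pair table; NA where undefined
pair_r <- function(pc, pairs) {
  ia <- match(pairs[[1]], pc$genes)
  ib <- match(pairs[[2]], pc$genes)
  ok <- !is.na(ia) & !is.na(ib)
  out <- rep(NA_real_, nrow(pairs))
  out[ok] <- pc$r[cbind(ia[ok], ib[ok])]
  out
}

all_defined_pairs <- function(pc) {
  idx <- which(upper.tri(pc$r) & !is.na(pc$r), arr.ind = TRUE)
  data.frame(gene_a = pc$genes[idx[, 1]], gene_b = pc$genes[idx[, 2]],
             r = pc$r[idx], stringsAsFactors = FALSE)
}

#' Contrast profile correlations of a gene-pair class against random pairs
#'
#' Compares the correlation values of a class of gene pairs (e.g. co-complex
#' pairs) to a size-matched random sample of defined pairs with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param pc A [profile_pcc()] result.
#' @param class_pairs Data.frame/list with two columns of gene ids.
#' @param n_random Random pairs to draw (default: size-matched).
#' @param rng_seed Optional seed for the random draw.
#' @return List with the class and random r samples, KS `D`, and `p`.
#' @export
class_contrast <- function(pc, class_pairs, n_random = NULL, rng_seed = NULL) {
  r_class <- pair_r(pc, class_pairs)
  r_class <- r_class[!is.na(r_class)]
  pool <- all_defined_pairs(pc)
  ## exclude the class pairs themselves from the background pool
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pool_r <- pool$r[!key(pool$gene_a, pool$gene_b) %in%
                     key(as.character(class_pairs[[1]]), as.character(class_pairs[[2]]))]
  if (length(r_class) < 5L || length(pool_r) < 5L)
    stop("need >= 5 defined correlations in each sample", call. = FALSE)
  if (is.null(n_random)) n_random <- length(r_class)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  r_rand <- sample(pool_r, min(n_random, length(pool_r)))
  ks <- suppressWarnings(stats::ks.test(r_class, r_rand))
  list(r_class = r_class, r_random = r_rand,
       D = unname(ks$statistic), p = ks$p.value)
}

#' Positional bias of profile correlation within operons
#'
#' For every operon with at least three members, compares the profile
#' correlation of its (first, last) gene pair with its (first, middle)
#' pairs. Polar effects of the marker insertion would depress downstream
#' (last-gene) correlations; similar distributions indicate no detectable
#' polarity artifact.
#'
#' @param pc A [profile_pcc()] result.
#' @param annotations Data.frame with `gene`, `operon_id`, `operon_pos`.
#' @return List with the two r samples, their means, KS and rank-sum p.
#' @export
operon_polarity <- function(pc, annotations) {
  an <- annotations[!is.na(annotations$operon_id), ]
  ops <- split(an[order(an$operon_pos), c("gene", "operon_pos")], an$operon_id[order(an$operon_pos)])
  ops <- ops[vapply(ops, nrow, 0L) >= 3L]
  if (length(ops) == 0L)
    stop("no operons of length >= 3", call. = FALSE)
  fl <- list(); fm <- list()
  for (op in ops) {
    first <- op$gene[1]; last <- op$gene[nrow(op)]
    mid <- op$gene[-c(1, nrow(op))]
    fl[[length(fl) + 1L]] <- data.frame(a = first, b = last)
    fm[[length(fm) + 1L]] <- data.frame(a = first, b = mid)
  }
  r_fl <- pair_r(pc, do.call(rbind, fl)); r_fl <- r_fl[!is.na(r_fl)]
  r_fm <- pair_r(pc, do.call(rbind, fm)); r_fm <- r_fm[!is.na(r_fm)]
  if (length(r_fl) < 2L || length(r_fm) < 2L)
    stop("not enough defined operon pair correlations", call. = FALSE)
  eq <- length(unique(c(r_fl, r_fm))) == 1L
  ks <- if (eq) list(statistic = c(D = 0), p.value = 1) else
    suppressWarnings(stats::ks.test(r_fl, r_fm))
  wt <- if (eq) list(p.value = 1) else
    suppressWarnings(stats::wilcox.test(r_fl, r_fm, exact = FALSE))
  list(r_first_last = r_fl, r_first_middle = r_fm,
       mean_difference = mean(r_fl) - mean(r_fm),
       D = unname(ks$statistic), p_ks = ks$p.value, p_ranksum = wt$p.value)
}

## canonical numeric pair keys over a node universe
pair_keys <- function(a, b, nodes) {
  ia <- match(a, nodes); ib <- match(b, nodes)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  (as.numeric(lo) - 1) * length(nodes) + hi
}

#' Overlap of the network with curated interaction pairs
#'
#' Fraction of curated pairs recovered as network edges, against a null of
#' size-matched random gene pairs drawn uniformly from the screened genes
#' (`n_perm` draws; optionally degree-matched by resampling endpoints from
#' the network's degree-weighted node list). The empirical p uses the
#' add-one estimator and therefore never reports zero.
#'
#' @param net A `gi_network`.
#' @param curated_pairs Data.frame with columns gene_a, gene_b and
#'   optionally `sign`; pairs must be among screened genes.
#' @param n_perm Number of null draws (default 10000; must be >= 1).
#' @param rng_seed Optional seed.
#' @param sign_aware Require the curated sign to match the edge sign.
#' @param degree_matched Draw null endpoints degree-weighted instead of
#'   uniformly.
#' @return List with `overlap` (fraction), `n_curated`, `null_overlap`
#'   (vector), `p`.
#' @export
literature_overlap <- function(net, curated_pairs, n_perm = 10000,
                               rng_seed = NULL, sign_aware = FALSE,
                               degree_matched = FALSE) {
  stopifnot(inherits(net, "gi_network"))
  if (is.null(curated_pairs) || nrow(curated_pairs) == 0L)
    stop("empty curated set", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  nodes <- net$nodes
  cur_a <- as.character(curated_pairs$gene_a)
  cur_b <- as.character(curated_pairs$gene_b)
  if (!all(c(cur_a, cur_b) %in% nodes))
    stop("curated pairs must be restricted to screened genes", call. = FALSE)
  k <- length(cur_a)
  edge_key <- pair_keys(net$edges$gene_a, net$edges$gene_b, nodes)
  if (sign_aware && !is.null(curated_pairs$sign)) {
    keys_by_sign <- split(edge_key, net$edges$sign)
    hit <- mapply(function(key, sgn) key %in% keys_by_sign[[sgn]],
                  pair_keys(cur_a, cur_b, nodes), curated_pairs$sign)
    observed <- mean(hit)
  } else {
    observed <- mean(pair_keys(cur_a, cur_b, nodes) %in% edge_key)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(nodes)
  draw_pool <- if (degree_matched) {
    match(c(net$edges$gene_a, net$edges$gene_b), nodes)
  } else {
    seq_len(n)
  }
  null_overlap <- vapply(seq_len(n_perm), function(i) {
    ia <- draw_pool[sample.int(length(draw_pool), k, replace = TRUE)]
    ib <- draw_pool[sample.int(length(draw_pool), k, replace = TRUE)]
    redo <- ia == ib
    while (any(redo)) {
      ib[redo] <- draw_pool[sample.int(length(draw_pool), sum(redo), replace = TRUE)]
      redo <- ia == ib
    }
    kk <- (pmin(ia, ib) - 1) * n + pmax(ia, ib)
    mean(kk %in% edge_key)
  }, numeric(1))
  p <- (1 + sum(null_overlap >= observed)) / (1 + n_perm)
  list(overlap = observed, n_curated = k, null_overlap = null_overlap, p = p)
}

#' Precision-recall curve over a score cutoff grid
#'
#' Sweeps a grid of cutoffs over pair scores (profile correlation or
#' co-conservation MI), computing precision and recall against a gold
#' standard of positive and negative pairs, and selects the smallest cutoff
#' whose precision reaches `precision_target`.
#'
#' @param scores Named interface: either a `profile_correlation` (pairs are
#'   pulled from it) or a data.frame with gene_a, gene_b, score.
#' @param gold List with `positive` and `negative` pair data.frames
#'   (columns gene_a, gene_b).
#' @param cutoffs Cutoff grid (default `seq(0, 0.9, by = 0.05)`).
#' @param precision_target Precision required of the selected cutoff
#'   (default 0.8).
#' @return List of class `pr_curve`: `curve` (data.frame: cutoff, tp, fp,
#'   precision, recall), `selected_cutoff` (NA with a warning if no cutoff
#'   reaches the target).
#' @export
pr_cutoff <- function(scores, gold, cutoffs = seq(0, 0.9, by = 0.05),
                      precision_target = 0.8) {
  if (is.null(gold$positive) || nrow(gold$positive) == 0L)
    stop("gold standard has no positive pairs", call. = FALSE)
  if (inherits(scores, "profile_correlation")) {
    s_pos <- pair_r(scores, gold$positive)
    s_neg <- pair_r(scores, gold$negative)
  } else {
    stopifnot(all(c("gene_a", "gene_b", "score") %in% names(scores)))
    key <- paste(pmin(scores$gene_a, scores$gene_b),
                 pmax(scores$gene_a, scores$gene_b))
    lk <- function(p) scores$score[match(paste(pmin(p[[1]], p[[2]]),
                                               pmax(p[[1]], p[[2]])), key)]
    s_pos <- lk(gold$positive)
    s_neg <- lk(gold$negative)
  }
  s_pos <- s_pos[!is.na(s_pos)]; s_neg <- s_neg[!is.na(s_neg)]
  if (length(s_pos) == 0L)
    stop("no positive gold pair has a defined score", call. = FALSE)
  curve <- data.frame(cutoff = cutoffs)
  curve$tp <- vapply(cutoffs, function(c) sum(s_pos >= c), 0)
  curve$fp <- vapply(cutoffs, function(c) sum(s_neg >= c), 0)
  curve$precision <- ifelse(curve$tp + curve$fp > 0,
                            curve$tp / (curve$tp + curve$fp), NA_real_)
  curve$recall <- curve$tp / length(s_pos)
  hit <- which(!is.na(curve$precision) & curve$precision >= precision_target)
  selected <- if (length(hit)) curve$cutoff[min(hit)] else NA_real_
  if (all(curve$tp == 0)) {
    warning("degenerate PR curve: no positives above any cutoff", call. = FALSE)
  } else if (is.na(selected)) {
    warning("no cutoff reaches the precision target", call. = FALSE)
  }
  out <- list(curve = curve, selected_cutoff = selected,
              precision_target = precision_target,
              n_pos = length(s_pos), n_neg = length(s_neg))
  class(out) <- "pr_curve"
  out
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d cutoffs, %d/%d gold pos/neg, selected cutoff %s (precision >= %.2f)\n",
              nrow(x$curve), x$n_pos, x$n_neg,
              ifelse(is.na(x$selected_cutoff), "none",
                     format(x$selected_cutoff)), x$precision_target))
  invisible(x)
}
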