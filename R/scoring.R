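#' Normalize colony-array plates
#'
#' All corrections are multiplicative. (i) Every plate median is scaled to
#' the experiment-wide median, absorbing batch/plate effects and the query
#' single-mutant growth rate. (ii) Row/column growth gradients — including
#' the nutrient edge boost on border rows/columns — are flattened by an
#' alternating strain/spatial fit in log space, pooled across all plate
#' instances of the same layout plate; computing the factors on
#' strain-corrected residuals keeps the long-tailed strain-fitness mixture
#' from bleeding into the spatial estimates on a fixed layout. (iii) Plate
#' scales are re-fit on strain-corrected residuals, and each layout plate
#' is anchored at the mode of its resident strain-fitness distribution
#' (layout-plate scale and strain fitness are otherwise confounded, since a
#' strain never changes plates). Zero colonies (absent/dead) are left at
#' zero and excluded from every estimate. Plates with more than
#' `reject_zero_frac` of their occupied positions at zero are rejected with
#' a warning.
#'
#' @param screen A `screen_plates` object (or list with `plates` and
#'   `layouts` in the same layout).
#' @param reject_zero_frac Zero-colony fraction above which a plate is
#'   dropped (default 0.5).
#' @return An object of class `normalized_plates`: list with `plates`
#'   (the normalized long data.frame), `layouts`, and `params`
#'   (per-plate scale factors, pooled row/column correction factors,
#'   global median, rejected plate ids).
#' @export
normalize_plates <- function(screen, reject_zero_frac = 0.5) {
  plates <- screen$plates
  layouts <- screen$layouts
  if (is.null(plates) || nrow(plates) == 0L)
    stop("no plates to normalize", call. = FALSE)
  ## occupancy from layout
  lkey <- paste(layouts$layout_plate, layouts$row, layouts$col)
  rec <- layouts$recipient[match(paste(plates$layout_plate, plates$row, plates$col), lkey)]
  occ <- !is.na(rec)

  ## plate rejection
  idx_by_plate <- split(seq_len(nrow(plates)), plates$plate_id)
  rejected <- character(0)
  for (pid in names(idx_by_plate)) {
    ii <- idx_by_plate[[pid]]
    o <- occ[ii]
    zero_frac <- if (any(o)) mean(plates$size[ii][o] == 0) else 1
    if (zero_frac > reject_zero_frac) {
      warning(sprintf("plate %s rejected: %.0f%% zero colonies", pid, 100 * zero_frac),
              call. = FALSE)
      rejected <- c(rejected, pid)
    }
  }
  if (length(rejected)) {
    keep <- !plates$plate_id %in% rejected
    plates <- plates[keep, ]
    rec <- rec[keep]; occ <- occ[keep]
    idx_by_plate <- split(seq_len(nrow(plates)), plates$plate_id)
  }
  if (nrow(plates) == 0L) stop("all plates rejected", call. = FALSE)

  ## pass 1: plate medians to the global median
  use <- occ & plates$size > 0
  plate_med_raw <- tapply(plates$size[use], plates$plate_id[use], stats::median)
  G <- stats::median(plates$size[use])
  plates$size <- plates$size / plate_med_raw[plates$plate_id] * G

  ## pass 2: row/column gradients (including the edge boost) by an
  ## alternating strain/spatial fit in log space. Row and column factors
  ## are pooled across all plate instances of the same layout plate:
  ## gradients are plate-geometry properties, and with a fixed layout a
  ## per-plate polish would confound the row's strain composition with its
  ## spatial factor. The alternation (strain effect given spatial, spatial
  ## given strain) converges to the joint robust fit; trimmed means guard
  ## against genuine-interaction and linkage outliers.
  lsz <- log(plates$size[use])
  strain <- factor(rec[use])
  rkey <- factor(paste(plates$layout_plate[use], plates$row[use]))
  ckey <- factor(paste(plates$layout_plate[use], plates$col[use]))
  min_cells <- 5L
  r_ok <- table(rkey) >= min_cells
  c_ok <- table(ckey) >= min_cells
  rowf <- stats::setNames(rep(0, nlevels(rkey)), levels(rkey))
  colf <- stats::setNames(rep(0, nlevels(ckey)), levels(ckey))
  tmean <- function(x) mean(x, trim = 0.2)
  for (iter in 1:8) {
    s_r <- tapply(lsz - rowf[rkey] - colf[ckey], strain, tmean)
    res <- lsz - s_r[strain] - colf[ckey]
    rf <- tapply(res, rkey, tmean)
    rf[!r_ok[names(rf)] | !is.finite(rf)] <- 0
    rowf <- rf - stats::median(rf)
    res <- lsz - s_r[strain] - rowf[rkey]
    cf <- tapply(res, ckey, tmean)
    cf[!c_ok[names(cf)] | !is.finite(cf)] <- 0
    colf <- cf - stats::median(cf)
  }
  plates$size[use] <- plates$size[use] / exp(rowf[rkey] + colf[ckey])

  ## per-plate scale from strain-corrected residuals (a raw plate median
  ## would carry the plate's strain composition)
  lsz <- log(plates$size[use])
  s_m <- tapply(lsz, strain, tmean)
  resid2 <- exp(lsz - s_m[strain])
  plate_med2 <- tapply(resid2, plates$plate_id[use], stats::median)
  plates$size <- plates$size / plate_med2[plates$plate_id]

  ## layout-plate anchoring: with a fixed layout, a strain never changes
  ## plates, so layout-plate scale and strain fitness are confounded; the
  ## anchor assumption is that every plate's resident strain-fitness
  ## distribution peaks at the no-defect (modal) level
  lsz <- log(plates$size[use])
  lp_use <- plates$layout_plate[use]
  m_lr <- tapply(lsz, paste(lp_use, rec[use], sep = "\r"), tmean)
  lr <- matrix(unlist(strsplit(names(m_lr), "\r", fixed = TRUE)), ncol = 2,
               byrow = TRUE)
  anchors <- tapply(m_lr, lr[, 1], function(v) {
    if (length(v) >= 30) robust_mode(v) else stats::median(v)
  })
  plates$size[use] <- plates$size[use] / exp(anchors[as.character(lp_use)])

  ## restore the global median
  plates$size <- as.numeric(plates$size / stats::median(plates$size[use]) * G)

  out <- list(
    plates = plates,
    layouts = layouts,
    params = list(
      plate_scale_factors = plate_med_raw / G,
      plate_raw_medians = plate_med_raw,
      row_corrections = exp(rowf),
      col_corrections = exp(colf),
      global_median = G,
      rejected = rejected,
      variance_floor = NA_real_
    )
  )
  class(out) <- "normalized_plates"
  out
}

#' @export
print.normalized_plates <- function(x, ...) {
  cat(sprintf("normalized_plates: %d plates, global median %.3g, %d rejected\n",
              length(unique(x$plates$plate_id)), x$params$global_median,
              length(x$params$rejected)))
  invisible(x)
}

## mode of a numeric sample: density peak, sharpened to the median of the
## values within one bandwidth of the peak so that a point-mass modal class
## is recovered exactly
robust_mode <- function(v) {
  d <- stats::density(v)
  m <- d$x[which.max(d$y)]
  near <- abs(v - m) <= d$bw
  if (any(near)) stats::median(v[near]) else m
}

## long table of (query, recipient, replicate, copy, size) for occupied,
## non-zero colonies
pair_observations <- function(norm) {
  plates <- norm$plates
  layouts <- norm$layouts
  lkey <- paste(layouts$layout_plate, layouts$row, layouts$col)
  rec <- layouts$recipient[match(paste(plates$layout_plate, plates$row, plates$col), lkey)]
  keep <- !is.na(rec) & plates$size > 0
  data.frame(
    query = plates$query[keep],
    recipient = rec[keep],
    replicate = plates$replicate[keep],
    copy = if (!is.null(plates$copy)) plates$copy[keep] else 1L,
    size = plates$size[keep],
    stringsAsFactors = FALSE
  )
}

## recipient fitness from an observation table: per-strain median size over
## the modal (no-defect) strain size; optionally excluding flagged
## interacting pairs so that genuine interactions do not bias the
## single-mutant estimate
fitness_from_obs <- function(obs, exclude = NULL) {
  tlmean <- function(x) exp(mean(log(x), trim = 0.05))
  ## reject gross low outliers relative to the strain's own median before
  ## estimating: linkage-suppressed and strongly aggravated colonies can
  ## exceed the trim fraction when a strain lies near several query loci
  lsz <- log(obs$size)
  med_r <- tapply(lsz, obs$recipient, stats::median)
  resid <- lsz - med_r[obs$recipient]
  obs <- obs[resid >= -3.5 * stats::mad(resid), ]
  ## trimmed log-scale mean: robust to interacting/linked partners,
  ## more efficient than the median at this replication depth
  rec_all <- tapply(obs$size, obs$recipient, tlmean)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(obs$query, obs$recipient) %in%
      paste(exclude$query, exclude$recipient)
    obs <- obs[!drop, ]
  }
  rec_med <- tapply(obs$size, obs$recipient, tlmean)
  ## recipients whose every pair was excluded keep the unexcluded estimate
  rec_med <- c(rec_med, rec_all[setdiff(names(rec_all), names(rec_med))])
  ref <- if (length(rec_med) >= 10) {
    exp(robust_mode(log(rec_med)))
  } else {
    stats::median(rec_med)
  }
  list(recipient = rec_med / ref, ref = ref)
}

#' Estimate single-mutant fitness from normalized plates
#'
#' Recipient fitness is the median normalized colony size of that strain
#' across all query screens divided by the reference strain size. The
#' reference is the mode of the per-strain median distribution (on the log
#' scale): in a rich-medium deletion collection the modal strain carries no
#' measurable defect, so the mode marks fitness 1 even though the global
#' median is dragged down by the sick minority. Because per-plate scaling
#' absorbs the query growth rate, query fitness is instead recovered from
#' the pre-scaling plate medians: the query's plate-set median relative to
#' its replicate batch median. Missing genes raise an error.
#'
#' @param norm A [normalize_plates()] result.
#' @param genes Optional genes to report (default: all observed recipients).
#' @return List with `recipient` (named fitness vector), `query` (named
#'   relative scale vector), `reference` (modal strain size), and
#'   `global_median`.
#' @export
estimate_single_fitness <- function(norm, genes = NULL) {
  obs <- pair_observations(norm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, unique(obs$recipient))
    if (length(missing))
      stop("gene(s) absent from all plates: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  G <- stats::median(obs$size)
  fo <- fitness_from_obs(obs)
  recipient <- fo$recipient
  ref <- fo$ref

  ## query scale from raw (pre plate-scaling) medians vs batch medians
  plates <- norm$plates
  meta <- unique(plates[, c("plate_id", "query", "replicate")])
  raw_med <- norm$params$plate_raw_medians[meta$plate_id]
  batch_med <- tapply(raw_med, meta$replicate, stats::median)
  rel <- raw_med / batch_med[as.character(meta$replicate)]
  query <- tapply(rel, meta$query, stats::median)

  list(recipient = recipient[order(names(recipient))],
       query = query[order(names(query))],
       reference = ref,
       global_median = G)
}

#' Expected double-mutant colony size under the multiplicative model
#'
#' Joint fitness defects of functionally unrelated genes combine
#' multiplicatively, so the neutral expectation for a double mutant is
#' `scale * f_query * f_recipient`.
#'
#' @param f_query,f_recipient Single-mutant fitness values (>= 0).
#' @param scale Reference colony size of a fully fit strain.
#' @return Expected colony size (vectorized).
#' @export
expected_size <- function(f_query, f_recipient, scale) {
  if (any(f_query < 0) || any(f_recipient < 0) || any(scale < 0))
    stop("fitness and scale must be non-negative", call. = FALSE)
  scale * f_query * f_recipient
}

#' Epistasis S-score for one gene pair
#'
#' A one-sample t-style statistic: the difference between the mean observed
#' double-mutant colony size and its multiplicative expectation, divided by
#' the standard error with the per-pair variance floored at an
#' experiment-wide value (the median within-pair variance), which stabilizes
#' the denominator at n = 8 measurements per pair.
#'
#' @param observed Numeric vector of replicate colony sizes (length >= 2).
#' @param expected Expected size under the multiplicative model.
#' @param variance_floor Experiment-wide variance floor.
#' @return The signed S-score; `NA` with a `low_n` attribute if fewer than
#'   two observations.
#' @export
s_score <- function(observed, expected, variance_floor) {
  n <- length(observed)
  if (n < 2L) {
    out <- NA_real_
    attr(out, "mask") <- "low_n"
    return(out)
  }
  v <- max(stats::var(observed), variance_floor)
  (mean(observed) - expected) / sqrt(v / n)
}

#' Score a screen into an S-score matrix
#'
#' The measurement unit is the plate-copy mean of the duplicate colonies
#' (duplicates are pinned from the same source position, so they are
#' averaged rather than treated as independent), giving
#' `n_replicate_screens * 2` independent units per pair. Per pair the
#' S-score is the deviation of the mean unit from its multiplicative
#' expectation over the floored standard error (see [s_score()]).
#' Recipient fitness is estimated, pairs scoring `|S| >= s_exclude` are
#' excluded, and fitness and scores are re-estimated once, so genuine
#' interactions do not contaminate the single-mutant estimates. The
#' expectation scale is calibrated as the median over pairs of mean
#' observed size over recipient fitness, centering the null S
#' distribution. `Z` standardizes S against the robust core
#' (median/MAD) of the score distribution, under which genuine
#' interactions are tail outliers.
#'
#' @param norm A [normalize_plates()] result.
#' @param s_exclude Threshold for the fitness-refinement exclusion
#'   (default 2.5: slightly wider than the network threshold, so borderline
#'   interactions cannot bias the single-mutant estimates).
#' @return An object of class `score_matrix`: list with matrices `S`, `Z`,
#'   `n_obs` (independent units per pair), `mask` (`"ok"`, `"low_n"`,
#'   `"missing"`, later `"linked"`), `queries`, `recipients`,
#'   `variance_floor`, `scale`, `fitness`.
#' @export
score_screens <- function(norm, s_exclude = 2.5) {
  obs <- pair_observations(norm)
  if (nrow(obs) == 0L) stop("no observations to score", call. = FALSE)
  ## plate-copy means: the independent measurement units
  ukey <- paste(obs$query, obs$recipient, obs$replicate, obs$copy, sep = "\r")
  uf <- factor(ukey)
  unit_mean <- as.vector(rowsum(obs$size, uf)) / as.vector(table(uf))
  uparts <- matrix(unlist(strsplit(levels(uf), "\r", fixed = TRUE)),
                   ncol = 4, byrow = TRUE)
  units <- data.frame(query = uparts[, 1], recipient = uparts[, 2],
                      size = unit_mean, stringsAsFactors = FALSE)

  queries <- sort(unique(obs$query))
  recipients <- sort(unique(obs$recipient))
  pid <- factor(paste(units$query, units$recipient, sep = "\r"))
  n_i <- as.vector(table(pid))
  sum_i <- as.vector(rowsum(units$size, pid))
  sum2_i <- as.vector(rowsum(units$size^2, pid))
  mean_i <- sum_i / n_i
  var_i <- ifelse(n_i >= 2, (sum2_i - n_i * mean_i^2) / pmax(1, n_i - 1), NA_real_)
  var_i <- pmax(var_i, 0)
  qr <- matrix(unlist(strsplit(levels(pid), "\r", fixed = TRUE)),
               ncol = 2, byrow = TRUE)
  q_lev <- qr[, 1]; r_lev <- qr[, 2]

  ## variance floor proportional to the squared expectation: colony noise
  ## is multiplicative, so the floor must scale with the pair's expected
  ## size or low-fitness pairs are over-floored and lose sensitivity
  rel_floor <- NA_real_
  score_pass <- function(f_rec) {
    f_r <- f_rec[r_lev]
    scale_hat <- stats::median(mean_i / f_r)
    expd <- expected_size(1, f_r, scale_hat)
    rel_floor <<- stats::median((var_i / expd^2)[n_i >= 2], na.rm = TRUE)
    floor_i <- rel_floor * expd^2
    list(S = ifelse(n_i >= 2,
                    (mean_i - expd) / sqrt(pmax(var_i, floor_i) / n_i),
                    NA_real_),
         scale = scale_hat)
  }
  fit1 <- fitness_from_obs(obs)
  p2 <- score_pass(fit1$recipient)
  ## two refinement rounds: re-estimate fitness without the pairs currently
  ## flagged as interacting, then rescore (the first pass's fitness is
  ## contaminated by strong interactions, attenuating their own scores)
  for (it in 1:2) {
    hits <- !is.na(p2$S) & abs(p2$S) >= s_exclude
    fit1 <- fitness_from_obs(obs, exclude = data.frame(query = q_lev[hits],
                                                       recipient = r_lev[hits]))
    p2 <- score_pass(fit1$recipient)
  }
  S_i <- p2$S

  fit <- estimate_single_fitness(norm)
  fit$recipient <- fit1$recipient[order(names(fit1$recipient))]
  fit$reference <- fit1$ref

  S <- matrix(NA_real_, length(queries), length(recipients),
              dimnames = list(queries, recipients))
  n_obs <- matrix(0L, length(queries), length(recipients),
                  dimnames = dimnames(S))
  mask <- matrix("missing", length(queries), length(recipients),
                 dimnames = dimnames(S))
  ij <- cbind(match(q_lev, queries), match(r_lev, recipients))
  S[ij] <- S_i
  n_obs[ij] <- n_i
  mask[ij] <- ifelse(n_i >= 2, "ok", "low_n")

  ## standardize against the null core of the score distribution (robust
  ## location/scale: true interactions sit in the tails and would inflate a
  ## moment-based sd)
  ok <- mask == "ok"
  Z <- S
  Z[ok] <- (S[ok] - stats::median(S[ok])) / stats::mad(S[ok])

  out <- list(S = S, Z = Z, n_obs = n_obs, mask = mask,
              queries = queries, recipients = recipients,
              variance_floor = rel_floor, scale = p2$scale, fitness = fit)
  class(out) <- "score_matrix"
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  tab <- table(x$mask)
  cat(sprintf("score_matrix: %d queries x %d recipients; mask: %s\n",
              length(x$queries), length(x$recipients),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Mask closely linked gene pairs
#'
#' Pairs whose loci lie within `window_bp` on the circular chromosome suffer
#' linkage suppression (reduced double-mutant recovery) and are excluded
#' from scoring. Pairs with a missing coordinate are left unmasked with a
#' warning.
#'
#' @param sm A [score_screens()] matrix.
#' @param coordinates Named coordinate vector (bp).
#' @param window_bp Masking window (default 30 kb).
#' @param chromosome_length_bp Circle length in bp.
#' @return The `score_matrix` with affected cells set to mask `"linked"`.
#' @export
mask_linked <- function(sm, coordinates, window_bp = 30000,
                        chromosome_length_bp = 4641652) {
  stopifnot(inherits(sm, "score_matrix"))
  cq <- coordinates[sm$queries]
  cr <- coordinates[sm$recipients]
  if (any(is.na(cq)) || any(is.na(cr))) {
    warning("missing coordinates; affected pairs left unmasked", call. = FALSE)
  }
  d <- outer(cq, cr, function(a, b) circular_distance(a, b, chromosome_length_bp))
  linked <- !is.na(d) & d < window_bp
  sm$mask[linked] <- "linked"
  sm
}

#' Threshold an S-score matrix into a signed interaction network
#'
#' Cells with mask `"ok"` and `S <= -s_cut` become aggravating edges,
#' `S >= +s_cut` alleviating edges (inclusive thresholds). When both
#' orientations of a pair were screened, the more extreme |S| wins. Masked
#' cells never become edges; self pairs are dropped.
#'
#' @param sm A `score_matrix`.
#' @param s_cut Threshold on |S| (default 3).
#' @return An object of class `gi_network`: list with `nodes` (all screened
#'   genes) and `edges` (data.frame: gene_a, gene_b, S, sign).
#' @export
threshold_network <- function(sm, s_cut = 3) {
  stopifnot(inherits(sm, "score_matrix"))
  ok <- sm$mask == "ok" & !is.na(sm$S) & abs(sm$S) >= s_cut
  idx <- which(ok, arr.ind = TRUE)
  ga <- sm$queries[idx[, 1]]
  gb <- sm$recipients[idx[, 2]]
  S <- sm$S[ok]
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]; S <- S[keep]
  a <- pmin(ga, gb); b <- pmax(ga, gb)
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    ord <- order(key, -abs(S))
    first <- !duplicated(key[ord])
    a <- a[ord][first]; b <- b[ord][first]; S <- S[ord][first]
  }
  edges <- data.frame(
    gene_a = a, gene_b = b, S = S,
    sign = ifelse(S <= 0, "aggravating", "alleviating"),
    stringsAsFactors = FALSE
  )
  gi_network(edges, nodes = union(sm$queries, sm$recipients))
}

#' Construct a signed genetic-interaction network
#'
#' @param edges Data.frame with columns gene_a, gene_b, S, sign (sign is
#'   derived from S when absent).
#' @param nodes Gene universe (defaults to the genes incident to edges);
#'   kept so permutation nulls can draw from all screened genes.
#' @return A `gi_network` object.
#' @export
gi_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "S") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b))
    stop("self-loops are not allowed in a gi_network", call. = FALSE)
  if (is.null(edges$sign))
    edges$sign <- ifelse(edges$S <= 0, "aggravating", "alleviating")
  bad <- (edges$sign == "aggravating" & edges$S > 0) |
    (edges$sign == "alleviating" & edges$S < 0)
  if (any(bad)) stop("edge sign inconsistent with S", call. = FALSE)
  if (is.null(nodes)) nodes <- union(edges$gene_a, edges$gene_b)
  out <- list(nodes = sort(unique(c(nodes, edges$gene_a, edges$gene_b))),
              edges = edges[, c("gene_a", "gene_b", "S", "sign")])
  class(out) <- "gi_network"
  out
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf("gi_network: %d nodes, %d edges (%d aggravating, %d alleviating)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "aggravating"),
              sum(x$edges$sign == "alleviating")))
  invisible(x)
}

#' Convert a gi_network to an igraph graph
#'
#' @param net A `gi_network`.
#' @param signed Keep `S` and `sign` as edge attributes (default TRUE).
#' @param isolates Include isolated (edge-free) screened genes.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net, signed = TRUE, isolates = TRUE) {
  stopifnot(inherits(net, "gi_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = if (isolates) data.frame(name = net$nodes) else NULL)
  if (!signed) g <- igraph::delete_edge_attr(
    igraph::delete_edge_attr(g, "S"), "sign")
  g
}

#' Per-replicate mean colony-size matrices
#'
#' @param norm A [normalize_plates()] result.
#' @return Named list (one per replicate screen) of query x recipient
#'   matrices of mean normalized colony sizes.
#' @export
replicate_size_matrices <- function(norm) {
  obs <- pair_observations(norm)
  queries <- sort(unique(obs$query)); recipients <- sort(unique(obs$recipient))
  lapply(split(obs, obs$replicate), function(d) {
    m <- matrix(NA_real_, length(queries), length(recipients),
                dimnames = list(queries, recipients))
    mu <- tapply(d$size, list(factor(d$query, queries), factor(d$recipient, recipients)),
                 mean)
    m[, ] <- mu
    m
  })
}

#' Reproducibility of replicate screens
#'
#' Pearson correlation between two replicate measurement matrices over the
#' cells defined (unmasked) in both.
#'
#' @param a,b Numeric matrices with identical dimensions (e.g. from
#'   [replicate_size_matrices()]), `NA` for masked/absent cells.
#' @param min_overlap Minimum shared cells (default 10).
#' @return Pearson r.
#' @export
replicate_correlation <- function(a, b, min_overlap = 10) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  shared <- !is.na(a) & !is.na(b)
  if (sum(shared) < min_overlap)
    stop(sprintf("insufficient overlap: %d shared cells (< %d)",
                 sum(shared), min_overlap), call. = FALSE)
  stats::cor(a[shared], b[shared])
}
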