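test_that("s_score matches its closed-form definition", {
  ## independent one-line evaluation: mean 0.30, var 2.6667e-4 < floor,
  ## S = (0.30 - 0.50) / sqrt(4e-4 / 4) = -20
  obs <- c(0.30, 0.28, 0.32, 0.30)
  expect_equal(s_score(obs, 0.50, 4e-4), -20, tolerance = 1e-9)
  ## above the floor the sample variance drives the score
  obs2 <- c(0.2, 0.4, 0.3, 0.5)
  oracle <- (mean(obs2) - 0.1) / sqrt(max(var(obs2), 1e-6) / 4)
  expect_equal(s_score(obs2, 0.1, 1e-6), oracle, tolerance = 1e-12)
})

test_that("s_score is antisymmetric about the expectation and zero at it", {
  obs <- c(0.42, 0.55, 0.47, 0.51)
  expected <- 0.6
  reflected <- 2 * expected - obs
  expect_equal(s_score(obs, expected, 1e-4),
               -s_score(reflected, expected, 1e-4), tolerance = 1e-12)
  expect_equal(s_score(rep(0.5, 4), 0.5, 1e-4), 0)
  low <- s_score(0.5, 0.4, 1e-4)
  expect_true(is.na(low))
  expect_equal(attr(low, "mask"), "low_n")
})

test_that("expected size is multiplicative with an absorbing zero", {
  expect_equal(expected_size(1.0, 0.6, 1.0), 0.6)
  expect_equal(expected_size(0.8, 0.5, 1.0), 0.4)
  expect_equal(expected_size(c(0.3, 1, 7), 0, c(1, 5, 100)), c(0, 0, 0))
  expect_error(expected_size(-0.1, 0.5, 1), "non-negative")
})

test_that("plate scaling equalizes plates differing by a global factor", {
  ## two copies of one plate, the second twice as large everywhere,
  ## normalize to identical values
  lay <- data.frame(layout_plate = 1L,
                    row = rep(1:4, each = 6), col = rep(1:6, 4),
                    recipient = sprintf("r%02d", rep(1:12, 2)),
                    dup_group = rep(1:12, 2), stringsAsFactors = FALSE)
  base <- 40 + 3 * rep(1:12, 2)
  mk <- function(id, copy, f) data.frame(
    plate_id = id, query = "q1", replicate = 1L, copy = copy,
    layout_plate = 1L, batch = 1L, row = lay$row, col = lay$col,
    size = base * f, stringsAsFactors = FALSE)
  plates <- rbind(mk("p_a", 1L, 1), mk("p_b", 2L, 2))
  norm <- normalize_plates(list(plates = plates, layouts = lay))
  a <- norm$plates$size[norm$plates$plate_id == "p_a"]
  b <- norm$plates$size[norm$plates$plate_id == "p_b"]
  expect_equal(a, b, tolerance = 1e-10)
  ## a whole-screen rescale propagates as a pure scale factor
  fx <- small_screen(42)
  scr <- simulate_plates(fx$truth, fx$cfg)
  scr2 <- scr
  scr2$plates$size <- scr2$plates$size * 2
  n1 <- normalize_plates(scr)
  n2 <- normalize_plates(scr2)
  expect_equal(2 * n1$plates$size, n2$plates$size, tolerance = 1e-10)
})

test_that("a uniform plate passes through normalization unchanged", {
  lay <- data.frame(layout_plate = 1L,
                    row = rep(1:4, each = 6), col = rep(1:6, 4),
                    recipient = sprintf("r%02d", rep(1:12, 2)),
                    dup_group = rep(1:12, 2), stringsAsFactors = FALSE)
  plates <- data.frame(plate_id = "q1_r1_c1_p01", query = "q1", replicate = 1L,
                       copy = 1L, layout_plate = 1L, batch = 1L,
                       row = lay$row, col = lay$col, size = 50,
                       stringsAsFactors = FALSE)
  norm <- normalize_plates(list(plates = plates, layouts = lay))
  expect_equal(unique(norm$plates$size), 50)
})

test_that("plates dominated by dead colonies are rejected with a warning", {
  fx <- small_screen(42)
  scr <- simulate_plates(fx$truth, fx$cfg)
  one <- unique(scr$plates$plate_id)[1]
  idx <- which(scr$plates$plate_id == one)
  scr$plates$size[idx[seq_len(ceiling(0.6 * length(idx)))]] <- 0
  expect_warning(norm <- normalize_plates(scr), "rejected")
  expect_false(one %in% norm$plates$plate_id)
})

test_that("spatial gradients are flattened by normalization", {
  fx <- small_screen(42)
  norm <- fx$norm
  obs <- giscreen:::pair_observations(norm)
  ## strain-corrected residual row medians (raw row medians would reflect
  ## the fixed strain composition of each row, not the spatial field)
  strain_med <- tapply(obs$size, obs$recipient, median)
  lay <- norm$layouts
  pp <- norm$plates
  rec <- lay$recipient[match(paste(pp$layout_plate, pp$row, pp$col),
                             paste(lay$layout_plate, lay$row, lay$col))]
  keep <- !is.na(rec) & pp$size > 0
  resid <- pp$size[keep] / strain_med[rec[keep]]
  row_med <- tapply(resid, pp$row[keep], median)
  expect_lt(max(row_med) / min(row_med), 1.04)
  col_med <- tapply(resid, pp$col[keep], median)
  expect_lt(max(col_med) / min(col_med), 1.04)
})

test_that("single-mutant fitness is recovered exactly on noise-free screens", {
  cfg <- screen_config(n_queries = 4, n_recipients = 80, rng_seed = 6,
                       noise_sd = 0, replicate_effect_sd = 0,
                       batch_effect_sd = 0, spatial_row_amp = 0,
                       spatial_col_amp = 0, edge_boost = 0,
                       frac_aggravating = 0, frac_alleviating = 0,
                       linkage_factor = 1)
  truth <- generate_ground_truth(cfg)
  norm <- normalize_plates(simulate_plates(truth, cfg))
  fit <- estimate_single_fitness(norm)
  tr <- stats::setNames(truth$genes$fitness, truth$genes$gene)
  expect_equal(unname(fit$recipient[names(fit$recipient)]),
               unname(tr[names(fit$recipient)]), tolerance = 1e-6)
  expect_error(estimate_single_fitness(norm, genes = "not_a_gene"), "absent")
})

test_that("linkage masking uses circular chromosome distance", {
  expect_equal(circular_distance(10e3, 20e3, 4.6e6), 10e3)
  expect_equal(circular_distance(10e3, 4590e3, 4600e3), 20e3)
  expect_equal(circular_distance(0.3e6, 2.3e6, 4.6e6), 2e6)
  S <- matrix(5, 2, 3, dimnames = list(c("q1", "q2"), c("r1", "r2", "r3")))
  sm <- fake_score_matrix(S)
  coords <- c(q1 = 10e3, q2 = 2.0e6, r1 = 20e3, r2 = 4.59e6, r3 = 2.3e6)
  sm2 <- mask_linked(sm, coords, window_bp = 30e3, chromosome_length_bp = 4.6e6)
  expect_equal(sm2$mask["q1", "r1"], "linked")   # 10 kb apart
  expect_equal(sm2$mask["q1", "r2"], "linked")   # 20 kb across the origin
  expect_equal(sm2$mask["q1", "r3"], "ok")       # ~2 Mb
  expect_equal(sm2$mask["q2", "r3"], "ok")       # 300 kb
  ## missing coordinate leaves the pair unmasked with a warning
  expect_warning(sm3 <- mask_linked(sm, coords[-3], window_bp = 30e3,
                                    chromosome_length_bp = 4.6e6),
                 "missing")
  expect_equal(sm3$mask["q1", "r2"], "linked")
})

test_that("thresholding is inclusive, sign-consistent and monotone", {
  S <- matrix(c(-3, 3, 2.9, -2.9, 8, -8), 1, 6,
              dimnames = list("q", paste0("r", 1:6)))
  sm <- fake_score_matrix(S)
  net <- threshold_network(sm, 3)
  expect_setequal(net$edges$gene_b[net$edges$sign == "aggravating"], c("r1", "r6"))
  expect_setequal(net$edges$gene_b[net$edges$sign == "alleviating"], c("r2", "r5"))
  expect_false(any(c("r3", "r4") %in% c(net$edges$gene_a, net$edges$gene_b)))
  ## masked cells never become edges
  sm$mask[1, 5] <- "linked"
  net2 <- threshold_network(sm, 3)
  expect_false("r5" %in% net2$edges$gene_b)
  ## monotone: raising the cutoff never adds edges
  for (cut in c(2, 3, 4, 9)) {
    e_lo <- nrow(threshold_network(sm, cut)$edges)
    e_hi <- nrow(threshold_network(sm, cut + 1)$edges)
    expect_lte(e_hi, e_lo)
  }
})

test_that("the two orientations of a pair merge by the more extreme score", {
  S <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  S["a", "b"] <- 4; S["b", "a"] <- -6
  sm <- fake_score_matrix(S)
  sm$mask[is.na(S)] <- "missing"
  net <- threshold_network(sm, 3)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$S, -6)
  expect_equal(net$edges$sign, "aggravating")
})

test_that("replicate correlation behaves at its anchors", {
  m <- matrix(rnorm(40), 5, 8)
  expect_equal(replicate_correlation(m, m), 1)
  expect_equal(replicate_correlation(m, -m), -1)
  m2 <- m; m2[] <- NA
  expect_error(replicate_correlation(m, m2), "overlap")
})

test_that("S is invariant to global rescaling of colony sizes", {
  fx <- small_screen(42)
  scr <- simulate_plates(fx$truth, fx$cfg)
  scr2 <- scr
  scr2$plates$size <- scr2$plates$size * 3.7
  s1 <- score_screens(normalize_plates(scr))
  s2 <- score_screens(normalize_plates(scr2))
  ok <- s1$mask == "ok"
  expect_equal(s1$S[ok], s2$S[ok], tolerance = 1e-8)
})
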