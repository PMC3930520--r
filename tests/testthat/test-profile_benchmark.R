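test_that("profile correlations hit their algebraic anchors", {
  S <- cbind(r1 = c(1, 0, -1), r2 = c(2, 0, -2), r3 = c(-1, 0, 1),
             r4 = c(0, 1, 0))
  rownames(S) <- paste0("q", 1:3)
  sm <- fake_score_matrix(S)
  pc <- profile_pcc(sm, min_overlap = 3)
  expect_equal(pc$r["r1", "r2"], 1)            # identical up to scale
  expect_equal(pc$r["r1", "r3"], -1)           # negated
  expect_equal(pc$r["r1", "r4"], 0)            # orthogonal by construction
  expect_true(all(abs(pc$r - t(pc$r)) < 1e-12, na.rm = TRUE))
  expect_equal(unname(diag(pc$r)), rep(1, 4))
})

test_that("sparse overlap and constant profiles yield undefined correlations", {
  S <- cbind(r1 = c(1, 2, NA, NA), r2 = c(NA, NA, 1, 2), r3 = c(1, 1, 1, 1),
             r4 = c(0, 1, 2, 3))
  rownames(S) <- paste0("q", 1:4)
  sm <- fake_score_matrix(S)
  sm$mask[is.na(S)] <- "missing"
  pc <- suppressWarnings(profile_pcc(sm, min_overlap = 2))
  expect_true(is.na(pc$r["r1", "r2"]))   # no shared queries
  expect_true(is.na(pc$r["r3", "r4"]))   # constant profile
  expect_equal(pc$n["r1", "r2"], 0)
})

test_that("KS statistic agrees with a brute-force ECDF sweep", {
  expect_equal(ks_D_brute(c(1, 2, 3), c(1.5, 2.5, 3.5)), 1 / 3)
  set.seed(31)
  r <- matrix(runif(900, -1, 1), 30, 30)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("g", 1:30), paste0("g", 1:30))
  pc <- fake_profile_correlation(r)
  cls <- data.frame(a = paste0("g", 1:10), b = paste0("g", 11:20))
  cc <- class_contrast(pc, cls, rng_seed = 5)
  expect_equal(cc$D, ks_D_brute(cc$r_class, cc$r_random), tolerance = 1e-12)
  ## degenerate anchors
  expect_equal(ks_D_brute(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_D_brute(c(1, 2), c(10, 11)), 1)
})

test_that("co-module profiles dominate random pairs on synthetic screens", {
  fx <- recovery_screen()
  pc <- profile_pcc(fx$sm, min_overlap = 10)
  md <- stats::setNames(fx$truth$genes$module_id, fx$truth$genes$gene)
  cm <- unique(c(fx$truth$couplings$module_a, fx$truth$couplings$module_b))
  grid <- expand.grid(a = pc$genes, b = pc$genes, stringsAsFactors = FALSE)
  grid <- grid[grid$a < grid$b, ]
  keep <- !is.na(md[grid$a]) & !is.na(md[grid$b]) &
    md[grid$a] == md[grid$b] & md[grid$a] %in% cm
  cc <- class_contrast(pc, grid[keep, ], rng_seed = 2)
  expect_gt(mean(cc$r_class), mean(cc$r_random))
  expect_lt(stats::wilcox.test(cc$r_class, cc$r_random,
                               alternative = "greater")$p.value, 0.01)
})

test_that("operon polarity finds no artifact in unpolarized screens", {
  ## degenerate anchor: all profiles identical -> both samples all 1
  r <- matrix(1, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  pc1 <- fake_profile_correlation(r)
  ann <- data.frame(gene = paste0("g", 1:6),
                    operon_id = rep(c("op1", "op2"), each = 3),
                    operon_pos = rep(1:3, 2))
  op <- operon_polarity(pc1, ann)
  expect_equal(op$mean_difference, 0)
  expect_gt(op$p_ks, 0.99)

  ## synthetic screens plant co-profiles for whole operons: no polarity
  fx <- recovery_screen()
  pc <- profile_pcc(fx$sm, min_overlap = 10)
  res <- operon_polarity(pc, fx$truth$genes)
  expect_gt(res$p_ks, 0.05)

  ## a planted polarity artifact is detected: decorrelate last genes
  r2 <- matrix(0.05, 40, 40, dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  diag(r2) <- 1
  ann2 <- data.frame(gene = paste0("g", 1:40),
                     operon_id = rep(sprintf("op%02d", 1:10), each = 4),
                     operon_pos = rep(1:4, 10))
  for (o in sprintf("op%02d", 1:10)) {
    g <- ann2$gene[ann2$operon_id == o]
    r2[g[1], g[2]] <- r2[g[2], g[1]] <- 0.8
    r2[g[1], g[3]] <- r2[g[3], g[1]] <- 0.8
    r2[g[1], g[4]] <- r2[g[4], g[1]] <- -0.6   # last gene anti-correlated
  }
  res2 <- operon_polarity(fake_profile_correlation(r2), ann2)
  expect_lt(res2$p_ranksum, 0.01)
  expect_lt(res2$mean_difference, 0)
})

test_that("literature overlap scores recovery and guards its inputs", {
  fx <- small_screen(42)
  set.seed(9)
  cur <- fx$net$edges[sample(nrow(fx$net$edges), 20), c("gene_a", "gene_b")]
  res <- literature_overlap(fx$net, cur, n_perm = 99, rng_seed = 1)
  expect_equal(res$overlap, 1)
  expect_lt(res$p, 0.05)
  expect_error(literature_overlap(fx$net, cur[0, ]), "empty")
  expect_error(literature_overlap(fx$net, cur, n_perm = 0), "n_perm")
  bad <- data.frame(gene_a = "not_screened", gene_b = cur$gene_b[1])
  expect_error(literature_overlap(fx$net, bad), "screened")
  ## sign-aware mode counts only matching signs
  cur2 <- fx$net$edges[1:10, c("gene_a", "gene_b", "sign")]
  cur2$sign <- ifelse(cur2$sign == "aggravating", "alleviating", "aggravating")
  res2 <- literature_overlap(fx$net, cur2, n_perm = 49, rng_seed = 1,
                             sign_aware = TRUE)
  expect_equal(res2$overlap, 0)
})

test_that("precision-recall cutoff selection behaves at its anchors", {
  scores <- data.frame(gene_a = sprintf("p%02d", 1:40),
                       gene_b = sprintf("q%02d", 1:40),
                       score = c(seq(0.6, 0.9, length.out = 20),
                                 seq(0.05, 0.35, length.out = 20)))
  gold <- list(positive = scores[1:20, 1:2], negative = scores[21:40, 1:2])
  pr <- pr_cutoff(scores, gold, cutoffs = seq(0, 0.9, 0.05),
                  precision_target = 1)
  sel <- pr$curve[pr$curve$cutoff == pr$selected_cutoff, ]
  expect_equal(sel$precision, 1)
  expect_equal(sel$recall, 1)
  ## shuffled labels: precision ~ prevalence at permissive cutoffs
  set.seed(8)
  lab <- sample(rep(c(TRUE, FALSE), 20))
  gold2 <- list(positive = scores[lab, 1:2], negative = scores[!lab, 1:2])
  pr2 <- suppressWarnings(pr_cutoff(scores, gold2, cutoffs = c(0, 0.05),
                                    precision_target = 0.99))
  expect_equal(pr2$curve$precision[1], 0.5, tolerance = 0.15)
  expect_error(pr_cutoff(scores, list(positive = scores[0, 1:2])), "no positive")
})

test_that("permutation p-values are valid under the null", {
  ## curated sets drawn from the null itself: P(p <= 0.05) stays near 0.05
  set.seed(123)
  nodes <- sprintf("g%03d", 1:150)
  ed <- unique(data.frame(gene_a = sample(nodes, 1500, TRUE),
                          gene_b = sample(nodes, 1500, TRUE)))
  ed <- ed[ed$gene_a != ed$gene_b, ][1:1000, ]
  ed$S <- sample(c(-4, 4), nrow(ed), TRUE)
  net <- gi_network(ed, nodes = nodes)
  rejections <- vapply(1:120, function(i) {
    k <- 120
    ia <- sample(nodes, k, TRUE); ib <- sample(nodes, k, TRUE)
    while (any(ia == ib)) ib[ia == ib] <- sample(nodes, sum(ia == ib), TRUE)
    res <- literature_overlap(net, data.frame(gene_a = ia, gene_b = ib),
                              n_perm = 99)
    res$p <= 0.05
  }, logical(1))
  ## validity bound: rejection rate <= alpha + 2/sqrt(n_perm)
  expect_lte(mean(rejections), 0.05 + 2 / sqrt(99))
})
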