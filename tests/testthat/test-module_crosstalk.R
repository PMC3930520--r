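test_that("module interaction counting follows the exclusion rule", {
  ed <- data.frame(gene_a = c("a", "a", "c", "x"),
                   gene_b = c("b", "c", "d", "y"),
                   S = c(-4, -4, 4, -5))
  net <- gi_network(ed)
  mods <- module_set(list(m1 = c("a", "b", "c"), m2 = c("x", "y")))
  cnt <- count_module_gis(net, mods)
  intra1 <- cnt[cnt$module_a == "m1" & cnt$module_b == "m1", ]
  expect_equal(intra1$n_total, 2L)              # a-b, a-c
  inter <- cnt[cnt$module_a == "m1" & cnt$module_b == "m2", ]
  expect_equal(inter$n_total, 0L)
  intra2 <- cnt[cnt$module_a == "m2" & cnt$module_b == "m2", ]
  expect_equal(intra2$n_total, 1L)              # x-y

  ## disjoint modules joined by one spanning edge
  mods2 <- module_set(list(m1 = c("a", "b"), m2 = c("d", "e")))
  net2 <- gi_network(data.frame(gene_a = "a", gene_b = "d", S = 3))
  cnt2 <- count_module_gis(net2, mods2)
  expect_equal(cnt2$n_total[cnt2$module_a == "m1" & cnt2$module_b == "m2"], 1L)

  ## genes shared by both modules are excluded from the pair's inter count
  mods3 <- module_set(list(m1 = c("a", "b", "c"), m2 = c("c", "d")))
  net3 <- gi_network(data.frame(gene_a = c("a", "c"), gene_b = c("c", "d"),
                                S = c(-4, -4)))
  cnt3 <- count_module_gis(net3, mods3)
  ## a-c has c in both modules; c-d has c shared: neither counts as inter
  expect_equal(cnt3$n_total[cnt3$module_a == "m1" & cnt3$module_b == "m2"], 0L)
})

test_that("random module counts equal the brute-force recount", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:40)
  ed <- unique(data.frame(gene_a = sample(genes, 150, TRUE),
                          gene_b = sample(genes, 150, TRUE)))
  ed <- ed[ed$gene_a != ed$gene_b, ][1:80, ]
  ed$S <- sample(c(-4, 4), 80, TRUE)
  net <- gi_network(ed, nodes = genes)
  mods <- module_set(list(m1 = sample(genes, 8), m2 = sample(genes, 10),
                          m3 = sample(genes, 6)))
  cnt <- count_module_gis(net, mods)
  for (i in seq_len(nrow(cnt))) {
    a <- cnt$module_a[i]; b <- cnt$module_b[i]
    oracle <- if (a == b) recount_intra(net$edges, mods$genes[[a]])
              else recount_inter(net$edges, mods$genes[[a]], mods$genes[[b]])
    expect_equal(cnt$n_aggravating[i], unname(oracle["aggravating"]))
    expect_equal(cnt$n_alleviating[i], unname(oracle["alleviating"]))
  }
  ## inter + intra never exceeds the edge total
  expect_lte(sum(cnt$n_total), nrow(net$edges) * length(mods))
})

test_that("permutation enrichment flags a planted dense pair", {
  set.seed(4)
  genes <- sprintf("g%03d", 1:120)
  m1 <- genes[1:8]; m2 <- genes[9:16]
  dense <- expand.grid(gene_a = m1[1:5], gene_b = m2[1:5],
                       stringsAsFactors = FALSE)[1:10, ]
  dense$S <- -5
  bg <- data.frame(gene_a = sample(genes[17:120], 60, TRUE),
                   gene_b = sample(genes[17:120], 60, TRUE))
  bg <- bg[bg$gene_a != bg$gene_b, ]
  bg <- bg[!duplicated(paste(pmin(bg$gene_a, bg$gene_b),
                             pmax(bg$gene_a, bg$gene_b))), ]
  bg$S <- sample(c(-4, 4), nrow(bg), TRUE)
  net <- gi_network(rbind(dense, bg), nodes = genes)
  mods <- module_set(list(m1 = m1, m2 = m2, m3 = genes[20:27]))
  res <- permutation_enrichment(net, mods, n_perm = 300, rng_seed = 6)
  hit <- res[res$module_a == "m1" & res$module_b == "m2", ]
  expect_gt(hit$Z, 2.5)
  expect_equal(hit$classification, "aggravating-enriched")
  ## a pair with no possible edges stays at p = 1
  nul <- res[res$module_a == "m2" & res$module_b == "m3", ]
  expect_equal(nul$p, 1)
})

test_that("null module assignments are not flagged", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:100)
  ed <- unique(data.frame(gene_a = sample(genes, 500, TRUE),
                          gene_b = sample(genes, 500, TRUE)))
  ed <- ed[ed$gene_a != ed$gene_b, ][1:300, ]
  ed$S <- sample(c(-4, 4), 300, TRUE)
  net <- gi_network(ed, nodes = genes)
  mods <- module_set(list(m1 = sample(genes, 10), m2 = sample(genes, 10)))
  res <- permutation_enrichment(net, mods, n_perm = 200, rng_seed = 9)
  expect_true(all(abs(res$Z) < 4, na.rm = TRUE))
})

test_that("the edge-rewiring null also flags a planted dense pair", {
  set.seed(4)
  genes <- sprintf("g%03d", 1:120)
  m1 <- genes[1:8]; m2 <- genes[9:16]
  dense <- expand.grid(gene_a = m1[1:5], gene_b = m2[1:5],
                       stringsAsFactors = FALSE)[1:10, ]
  dense$S <- -5
  bg <- data.frame(gene_a = sample(genes[17:120], 60, TRUE),
                   gene_b = sample(genes[17:120], 60, TRUE))
  bg <- bg[bg$gene_a != bg$gene_b, ]
  bg <- bg[!duplicated(paste(pmin(bg$gene_a, bg$gene_b),
                             pmax(bg$gene_a, bg$gene_b))), ]
  bg$S <- sample(c(-4, 4), nrow(bg), TRUE)
  net <- gi_network(rbind(dense, bg), nodes = genes)
  mods <- module_set(list(m1 = m1, m2 = m2))
  res <- permutation_enrichment(net, mods, n_perm = 200, rng_seed = 8,
                                null = "edge_rewire")
  hit <- res[res$module_a == "m1" & res$module_b == "m2", ]
  expect_gt(hit$Z, 2.5)
  expect_equal(hit$classification, "aggravating-enriched")
})

test_that("Jaccard similarity of interactor sets", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("x"),
               D = character(0), E = character(0))
  J <- shared_interactor_jaccard(sets)
  expect_equal(J["A", "B"], 0.5)        # |int| 2 / |union| 4
  expect_equal(J["A", "C"], 0)
  expect_equal(J["A", "A"], 1)
  expect_true(is.na(J["D", "E"]))
  expect_equal(J, t(J))
  expect_true(all(J >= 0 & J <= 1, na.rm = TRUE))
})

test_that("per-gene census counts degrees and exclusive partners", {
  ## star on a listed gene: all leaves exclusive to it
  ed <- data.frame(gene_a = "hub", gene_b = sprintf("leaf%d", 1:5),
                   S = c(-4, -4, 4, 4, 4))
  net <- gi_network(ed)
  res <- per_gene_interaction_census(net, c("hub", "other"))
  hub <- res$census[res$census$gene == "hub", ]
  expect_equal(hub$n_aggravating, 2L)
  expect_equal(hub$n_alleviating, 3L)
  expect_equal(hub$n_exclusive_partners, 5L)
  oth <- res$census[res$census$gene == "other", ]
  expect_equal(oth$n_total, 0L)
  ## random network census equals a direct recount
  set.seed(33)
  genes <- sprintf("g%02d", 1:20)
  ed2 <- unique(data.frame(gene_a = sample(genes, 60, TRUE),
                           gene_b = sample(genes, 60, TRUE)))
  ed2 <- ed2[ed2$gene_a != ed2$gene_b, ]
  ed2$S <- sample(c(-3, 3), nrow(ed2), TRUE)
  net2 <- gi_network(ed2)
  listed <- genes[1:6]
  res2 <- per_gene_interaction_census(net2, listed)
  for (g in listed) {
    deg <- sum(ed2$gene_a == g) + sum(ed2$gene_b == g)
    expect_equal(res2$census$n_total[res2$census$gene == g], deg)
  }
})

test_that("chaperone family crosstalk p-values match enumeration", {
  genes <- c(paste0("h70_", 1:4), paste0("h100_", 1:3), paste0("prot_", 1:3))
  fam <- data.frame(gene = genes,
                    family = c(rep("Hsp70", 4), rep("Hsp100", 3),
                               rep("protease", 3)))
  ed <- data.frame(gene_a = c("h70_1", "h70_2", "h70_1", "prot_1"),
                   gene_b = c("h100_1", "h100_2", "h70_3", "prot_2"),
                   S = c(-4, -4, 4, -4))
  net <- gi_network(ed, nodes = genes)
  res <- chaperone_family_crosstalk(net, fam, p_max = 0.09)
  row <- res[res$family_a == "Hsp100" & res$family_b == "Hsp70", ]
  expect_equal(row$n_total, 2L)
  N <- choose(10, 2); K <- 4 * 3; n <- 4
  expect_equal(row$p, hyper_tail_enum(2, K, N, n), tolerance = 1e-10)
  ## family pair with zero interactions -> p = 1
  z <- res[res$family_a == "Hsp100" & res$family_b == "protease", ]
  expect_equal(z$p, 1)
  expect_error(chaperone_family_crosstalk(net, data.frame(gene = "x", family = "")),
               "family")
})
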