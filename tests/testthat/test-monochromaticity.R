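test_that("monochromatic score anchors, symmetry and scaling", {
  expect_equal(monochromatic_score(5, 0), -1)
  expect_equal(monochromatic_score(0, 7), 1)
  expect_equal(monochromatic_score(4, 4), 0)
  expect_error(monochromatic_score(0, 0), "undefined")
  expect_error(monochromatic_score(-1, 2), "non-negative")
  ## antisymmetry and scale invariance over a grid
  for (a in 0:6) {
    for (b in 0:6) {
      if (a + b == 0) next
      expect_equal(monochromatic_score(a, b), -monochromatic_score(b, a))
      expect_equal(monochromatic_score(3 * a, 3 * b), monochromatic_score(a, b))
      expect_true(abs(monochromatic_score(a, b)) <= 1)
      expect_equal(abs(monochromatic_score(a, b)) == 1, a == 0 || b == 0)
    }
  }
})

test_that("process pair counting handles single and multi-label genes", {
  net <- gi_network(data.frame(gene_a = "g1", gene_b = "g2", S = -4))
  ann <- data.frame(gene = c("g1", "g2"), process = c("A", "B"))
  res <- process_pair_counts(net, ann)
  expect_equal(nrow(res), 1L)
  expect_equal(res$process_a, "A")
  expect_equal(res$process_b, "B")
  expect_equal(res$n_aggravating, 1L)
  expect_equal(res$n_alleviating, 0L)

  ## a gene labeled A|B with a partner labeled A contributes to (A,A) and (A,B)
  ann2 <- data.frame(gene = c("g1", "g2"), process = c("A|B", "A"))
  res2 <- process_pair_counts(net, ann2)
  expect_setequal(paste(res2$process_a, res2$process_b), c("A A", "A B"))
  expect_equal(res2$n_aggravating, c(1L, 1L))

  ## unannotated genes are ignored
  ann3 <- data.frame(gene = c("g1", "g2"), process = c("A", NA))
  expect_equal(nrow(process_pair_counts(net, ann3)), 0L)
})

test_that("random label assignments match a brute-force recount", {
  set.seed(77)
  genes <- sprintf("g%02d", 1:25)
  ed <- unique(data.frame(gene_a = sample(genes, 60, TRUE),
                          gene_b = sample(genes, 60, TRUE)))
  ed <- ed[ed$gene_a != ed$gene_b, ][1:40, ]
  ed$S <- sample(c(-5, 5), 40, TRUE)
  net <- gi_network(ed)
  labs <- replicate(25, sample(LETTERS[1:4], sample(0:2, 1)), simplify = FALSE)
  names(labs) <- genes
  res <- process_pair_counts(net, labs)
  ## independent triple loop
  for (i in seq_len(nrow(res))) {
    pa <- res$process_a[i]; pb <- res$process_b[i]
    agg <- 0L; all_ <- 0L
    for (k in seq_len(nrow(net$edges))) {
      la <- labs[[net$edges$gene_a[k]]]; lb <- labs[[net$edges$gene_b[k]]]
      hit <- (pa %in% la && pb %in% lb) || (pa %in% lb && pb %in% la)
      if (hit) {
        if (net$edges$sign[k] == "aggravating") agg <- agg + 1L else all_ <- all_ + 1L
      }
    }
    expect_equal(res$n_aggravating[i], agg)
    expect_equal(res$n_alleviating[i], all_)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:30)
  ed <- unique(data.frame(gene_a = sample(genes, 80, TRUE),
                          gene_b = sample(genes, 80, TRUE)))
  ed <- ed[ed$gene_a != ed$gene_b, ][1:30, ]
  ed$S <- sample(c(-5, 5), 30, TRUE)
  net <- gi_network(ed, nodes = genes)
  ann <- data.frame(gene = genes,
                    process = sample(c("A", "B", "C"), 30, TRUE))
  counts <- process_pair_counts(net, ann)
  res <- pair_enrichment(counts, net, ann)
  ## rebuild the urn from scratch and enumerate the tail
  size <- table(unlist(strsplit(ann$process, "|", fixed = TRUE)))
  n_genes <- length(genes)
  N_pairs <- choose(n_genes, 2)
  n_edges <- nrow(ed)
  for (i in seq_len(nrow(res))) {
    a <- res$process_a[i]; b <- res$process_b[i]
    K <- if (a == b) choose(size[[a]], 2) else size[[a]] * size[[b]]
    k <- res$n_aggravating[i] + res$n_alleviating[i]
    expect_equal(res$p[i], hyper_tail_enum(k, K, N_pairs, n_edges),
                 tolerance = 1e-10)
  }
  ## q-values are a monotone BH adjustment of p
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
})

test_that("degenerate enrichment cases behave correctly", {
  ## categories with no tested genes in the network -> p = 1
  net <- gi_network(data.frame(gene_a = "g1", gene_b = "g2", S = -4))
  ann <- data.frame(gene = c("g1", "g2"), process = c("A", "A"))
  counts <- process_pair_counts(net, ann)
  counts <- rbind(counts,
                  data.frame(process_a = "X", process_b = "Y",
                             n_aggravating = 0L, n_alleviating = 0L, M = NA))
  res <- pair_enrichment(counts, net, ann)
  expect_equal(res$p[res$process_a == "X"], 1)

  ## all edges concentrated in one pair -> that pair has the smallest p
  set.seed(11)
  genes <- sprintf("g%02d", 1:20)
  ed <- expand.grid(gene_a = genes[1:5], gene_b = genes[6:10],
                    stringsAsFactors = FALSE)
  ed$S <- -4
  net2 <- gi_network(ed, nodes = genes)
  ann2 <- data.frame(gene = genes, process = rep(c("A", "B", "C", "D"), each = 5))
  counts2 <- process_pair_counts(net2, ann2)
  res2 <- pair_enrichment(counts2, net2, ann2)
  expect_equal(paste(res2$process_a[which.min(res2$p)],
                     res2$process_b[which.min(res2$p)]), "A B")
})

test_that("permutation enrichment p agrees qualitatively with hypergeometric", {
  fx <- small_screen(42)
  ann <- data.frame(gene = fx$truth$genes$gene, process = fx$truth$genes$process)
  counts <- process_pair_counts(fx$net, ann)
  hy <- pair_enrichment(counts, fx$net, ann, method = "hypergeometric")
  pe <- pair_enrichment(counts, fx$net, ann, method = "permutation",
                        n_perm = 200, rng_seed = 3)
  ## strongly enriched pairs under one method are enriched under the other
  strong <- which(hy$p < 0.001)
  expect_true(all(pe$p[strong] < 0.05))
})

test_that("planted module couplings are recovered with the planted sign", {
  fx <- recovery_screen()
  ## use module membership as the category annotation
  ann <- data.frame(gene = fx$truth$genes$gene,
                    process = fx$truth$genes$module_id)
  counts <- process_pair_counts(fx$net, ann)
  res <- pair_enrichment(counts, fx$net, ann)
  coup <- fx$truth$couplings
  for (i in seq_len(nrow(coup))) {
    a <- min(coup$module_a[i], coup$module_b[i])
    b <- max(coup$module_a[i], coup$module_b[i])
    row <- res[res$process_a == a & res$process_b == b, ]
    if (nrow(row) == 1 && row$p <= 0.05) {
      expect_equal(sign(row$M),
                   if (coup$sign[i] == "aggravating") -1 else 1,
                   label = sprintf("sign of M for %s-%s", a, b))
    }
  }
  ## and at least half the couplings are significantly enriched
  sig <- vapply(seq_len(nrow(coup)), function(i) {
    a <- min(coup$module_a[i], coup$module_b[i])
    b <- max(coup$module_a[i], coup$module_b[i])
    row <- res[res$process_a == a & res$process_b == b, ]
    nrow(row) == 1 && !is.na(row$p) && row$p <= 0.05
  }, logical(1))
  expect_gt(mean(sig), 0.5)
})
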