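#!/usr/bin/env Rscript
# Stage 7 — evolutionary co-conservation: mutual information over binary
# phylogenetic profiles (233 genomes in three relatedness groups),
# precision-recall selection of the MI cutoff, integration with GI-profile
# correlation into co-conserved correlated clusters, and per-group
# conservation fractions.

library(giscreen)

dat <- file.path("results", "data")
out <- "results"
prof <- read_profiles(file.path(dat, "phylo_profiles.tsv"))
print(prof)
sm <- read_score_matrix(file.path(out, "scores.tsv"))
ann <- read_annotations(file.path(dat, "genes.tsv"))

mi <- profile_mi(prof)
pc <- profile_pcc(sm, min_overlap = 10)

## MI cutoff by precision-recall against co-module gold standard
md <- setNames(ann$module_id, ann$gene)
genes <- intersect(rownames(mi), pc$genes)
grid <- expand.grid(gene_a = genes, gene_b = genes, stringsAsFactors = FALSE)
grid <- grid[grid$gene_a < grid$gene_b, ]
pos <- grid[!is.na(md[grid$gene_a]) & !is.na(md[grid$gene_b]) &
              md[grid$gene_a] == md[grid$gene_b], ]
set.seed(108)
neg_pool <- grid[!is.na(md[grid$gene_a]) & !is.na(md[grid$gene_b]) &
                   md[grid$gene_a] != md[grid$gene_b], ]
neg <- neg_pool[sample(nrow(neg_pool), min(10 * nrow(pos), nrow(neg_pool))), ]
pr <- mi_cutoff_pr(mi, list(positive = pos, negative = neg),
                   cutoffs = seq(0, 1, by = 0.05), precision_target = 0.5)
print(pr)
write.table(pr$curve, file.path(out, "mi_pr_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## co-conserved correlated clusters (and anti-correlated co-conserved pairs)
ut <- cbind(match(grid$gene_a, rownames(mi)), match(grid$gene_b, rownames(mi)))
up <- cbind(match(grid$gene_a, pc$genes), match(grid$gene_b, pc$genes))
pairs <- data.frame(gene_a = grid$gene_a, gene_b = grid$gene_b,
                    r = pc$r[up], mi = mi[ut])
cl <- coconserved_clusters(pairs, pcc_min = 0.5, mi_min = 0.2, anti_max = -0.5)
print(cl)
write.table(cl$clusters, file.path(out, "coconserved_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(cl$clusters)) {
  cat("largest clusters:\n")
  print(head(cl$clusters[order(-cl$clusters$n_genes), ], 5), row.names = FALSE)
}

## within- vs between-module co-conservation
ppos <- pairs[paste(pairs$gene_a, pairs$gene_b) %in% paste(pos$gene_a, pos$gene_b), ]
cat(sprintf("mean MI within modules %.3f vs between %.3f\n",
            mean(ppos$mi), mean(pairs$mi[!paste(pairs$gene_a, pairs$gene_b) %in%
                                           paste(pos$gene_a, pos$gene_b)])))

## conservation fractions by genome group
for (g in unique(prof$genome_group)) {
  cf <- conservation_fraction(prof, group = g)
  cat(sprintf("mean conservation in %s genomes: %.2f\n", g, cf$mean))
}
cat("wrote mi_pr_curve.tsv, coconserved_clusters.tsv\n")
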