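#!/usr/bin/env Rscript
# Stage 6 — module crosstalk: permutation Z-scores for intra- and
# inter-module interaction enrichment, plus the gene-panel statistics used
# for chaperone-style families: per-gene interaction census with exclusive
# partners, Jaccard overlap of interactor sets, and family-pair
# hypergeometric crosstalk.

library(giscreen)

dat <- file.path("results", "data")
out <- "results"
net <- read_edge_list(file.path(out, "gi_network.tsv"))
ann <- read_annotations(file.path(dat, "genes.tsv"))
mods <- read_gmt(file.path(dat, "modules.gmt"))

enr <- permutation_enrichment(net, mods, n_perm = 1000, z_min = 2.5,
                              p_max = 0.05, min_edges = 3, rng_seed = 107)
write.table(enr, file.path(out, "module_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- enr[enr$classification != "ns", ]
cat(sprintf("%d significant module-pair enrichments (Z >= 2.5, p <= 0.05): %d aggravating, %d alleviating; %d intra-module\n",
            nrow(sig), sum(sig$classification == "aggravating-enriched"),
            sum(sig$classification == "alleviating-enriched"), sum(sig$intra)))
print(head(sig[order(-sig$Z), c("module_a", "module_b", "intra", "n_total",
                                "null_mean", "Z", "p", "classification")], 8),
      row.names = FALSE)

## gene-panel statistics on the essential (hypomorph-built) modules, the
## synthetic analog of a chaperone/protease panel: families = modules
ess_mods <- mods$id[vapply(mods$genes, function(g) {
  mean(ann$class[match(g, ann$gene)] == "hypomorph") >= 0.5
}, logical(1))]
if (length(ess_mods) >= 1) {
  panel <- unlist(mods$genes[ess_mods])
  census <- per_gene_interaction_census(net, panel)
  write.table(census$census, file.path(out, "panel_census.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("panel census: per-gene interaction counts range %d-%d; %d exclusive partners in total\n",
              min(census$census$n_total), max(census$census$n_total),
              sum(census$census$n_exclusive_partners)))

  fam <- data.frame(gene = panel,
                    family = rep(ess_mods, lengths(mods$genes[ess_mods])))
  if (length(ess_mods) >= 2) {
    ct <- chaperone_family_crosstalk(net, fam, p_max = 0.09)
    write.table(ct, file.path(out, "family_crosstalk.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("family crosstalk: %d of %d family pairs significant at p <= 0.09\n",
                sum(ct$significant), nrow(ct)))
  }

  ## shared non-panel interactors between panel-containing modules
  sets <- lapply(mods$genes[ess_mods], function(g) {
    partners <- unique(unlist(per_gene_interaction_census(net, g)$exclusive_partners))
    setdiff(partners, panel)
  })
  if (length(sets) >= 2) {
    J <- shared_interactor_jaccard(sets)
    cat("Jaccard overlap of exclusive interactor sets:\n")
    print(round(J, 3))
  }
}
cat("wrote module_enrichment.tsv, panel_census.tsv\n")
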