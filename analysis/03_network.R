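#!/usr/bin/env Rscript
# Stage 3 — threshold the score matrix into a signed GI network and
# characterize its topology: signed degrees, clustering, betweenness,
# hubs, essential-vs-non-essential centrality, and the aggravating /
# alleviating balance within essential vs non-essential complexes.

library(giscreen)

dat <- file.path("results", "data")
out <- "results"
sm <- read_score_matrix(file.path(out, "scores.tsv"))
ann <- read_annotations(file.path(dat, "genes.tsv"))
mods <- read_gmt(file.path(dat, "modules.gmt"))

net <- threshold_network(sm, s_cut = 3)
print(net)
write_edge_list(net, file.path(out, "gi_network.tsv"))

## hub threshold scaled to the desk-size screen (the genome-scale default
## of 640 presumes thousands of tested partners)
topo <- gi_topology(net, hub_min_degree = 30)
print(topo)
write.table(topo$node_stats, file.path(out, "node_topology.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("average clustering coefficient = %.3f; %d hubs at degree >= 30\n",
            topo$acc, length(topo$hubs)))

ess <- essentiality_contrast(topo, ann)
cat(sprintf("median degree essential %.1f vs non-essential %.1f (rank-sum p = %.3g)\n",
            ess$median_degree[["essential"]], ess$median_degree[["non_essential"]],
            ess$p_degree))
cat(sprintf("median betweenness essential %.2g vs non-essential %.2g (p = %.3g)\n",
            ess$median_betweenness[["essential"]],
            ess$median_betweenness[["non_essential"]], ess$p_betweenness))

csr <- complex_sign_ratio(net, mods, ann)
cat("within-complex sign table (rows: complex essentiality):\n")
print(csr$table)
cat(sprintf("aggravating:alleviating ratio, essential %.2f vs non-essential %.2f; Fisher p = %.3g\n",
            csr$ratio[["essential"]], csr$ratio[["non_essential"]], csr$p))

summary_df <- data.frame(
  metric = c("n_edges", "n_aggravating", "n_alleviating", "acc", "n_hubs",
             "p_degree_essentiality", "p_fisher_complex_sign"),
  value = c(nrow(net$edges), sum(net$edges$sign == "aggravating"),
            sum(net$edges$sign == "alleviating"), topo$acc, length(topo$hubs),
            ess$p_degree, csr$p))
write.table(summary_df, file.path(out, "network_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote gi_network.tsv, node_topology.tsv, network_summary.tsv\n")
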