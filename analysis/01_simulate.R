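#!/usr/bin/env Rscript
# Stage 1 — simulate a genetic-interaction screen with known ground truth.
#
# Generates the desk-scale study condition used throughout the analysis:
# 20 query donors x 400 recipients, 384-colony plates arrayed in duplicate,
# two replicate screens (8 measurements per pair), planted aggravating /
# alleviating epistasis concentrated in coupled functional modules, plate
# gradients, batch wobble and linkage suppression. Everything downstream
# runs from the files written here.

library(giscreen)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- screen_config(n_queries = 20, n_recipients = 400, rng_seed = 20)
print(cfg)

truth <- generate_ground_truth(cfg)
print(truth)
scr <- simulate_plates(truth, cfg)
print(scr)

write_plates(scr$plates, file.path(out, "plates.tsv"))
write_layout(scr$layouts, file.path(out, "layout.tsv"))
write_ground_truth(truth, out)
prof <- generate_phylo_profiles(truth, rng_seed = cfg$rng_seed + 7L)
write_profiles(prof, file.path(out, "phylo_profiles.tsv"))

n_agg <- sum(truth$epsilon$epsilon < 0)
cat(sprintf(
  "planted interactions: %d aggravating, %d alleviating (%d coupled to %d module pairs)\n",
  n_agg, nrow(truth$epsilon) - n_agg, sum(truth$epsilon$coupled),
  nrow(truth$couplings)))
cat("wrote plates, layout, ground truth and phylogenetic profiles to", out, "\n")
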