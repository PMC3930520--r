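#!/usr/bin/env Rscript
# Stage 2 — normalize plates and compute epistasis S-scores.
#
# Reads the raw plate files from stage 1, corrects plate scale, spatial
# gradients and edge effects, estimates single-mutant fitness, scores every
# pair under the multiplicative model, masks linked loci, and reports
# replicate reproducibility and recovery against the simulation truth.

library(giscreen)

dat <- file.path("results", "data")
out <- "results"
plates <- read_plates(file.path(dat, "plates.tsv"))
layouts <- read_layout(file.path(dat, "layout.tsv"))
ann <- read_annotations(file.path(dat, "genes.tsv"))

norm <- normalize_plates(list(plates = plates, layouts = layouts))
print(norm)

sm <- score_screens(norm)
coords <- setNames(ann$coordinate, ann$gene)
sm <- mask_linked(sm, coords, window_bp = 30000,
                  chromosome_length_bp = 4641652)
print(sm)
write_score_matrix(sm, file.path(out, "scores.tsv"))

fit_df <- data.frame(gene = names(sm$fitness$recipient),
                     fitness = as.numeric(sm$fitness$recipient))
write_annotations(fit_df, file.path(out, "fitness_estimates.tsv"))

## replicate-screen reproducibility (pair mean colony sizes)
rs <- replicate_size_matrices(norm)
r <- replicate_correlation(rs[[1]], rs[[2]])
cat(sprintf("replicate-screen reproducibility r = %.3f\n", r))

## recovery against the simulation truth
truth_fit <- setNames(ann$fitness, ann$gene)
rel <- abs(fit_df$fitness - truth_fit[fit_df$gene]) / truth_fit[fit_df$gene]
cat(sprintf("single-mutant fitness within 5%% of truth: %.1f%% of genes\n",
            100 * mean(rel <= 0.05)))

eps <- read_epsilon(file.path(dat, "epsilon.tsv"))
big <- abs(eps$epsilon) >= 0.5
ii <- cbind(match(eps$query, sm$queries), match(eps$recipient, sm$recipients))
called <- !is.na(sm$S[ii]) & sm$mask[ii] == "ok" & abs(sm$S[ii]) >= 3 &
  sign(sm$S[ii]) == sign(eps$epsilon)
cat(sprintf("planted |epsilon| >= 0.5 pairs called with correct sign at |S| >= 3: %.1f%%\n",
            100 * mean(called[big])))

ok <- sm$mask == "ok"
summary_df <- data.frame(
  metric = c("replicate_r", "fitness_within_5pct", "sign_recovery_strong",
             "mean_S", "sd_S", "mad_S", "frac_abs_S_ge_3"),
  value = c(r, mean(rel <= 0.05), mean(called[big]),
            mean(sm$S[ok]), sd(sm$S[ok]), mad(sm$S[ok]),
            mean(abs(sm$S[ok]) >= 3)))
write.table(summary_df, file.path(out, "scoring_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote scores.tsv (+mask/nobs), fitness_estimates.tsv, scoring_summary.tsv\n")
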