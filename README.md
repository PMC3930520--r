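# giscreen

Analysis of genome-wide bacterial genetic-interaction (GI) screens of the
eSGA kind: conjugation-based construction of double mutants between a
panel of query donor genes and an arrayed, genome-wide recipient
collection, read out as colony sizes on 384-colony plates. The package is
for people who run or reanalyze such screens — and for methodologists who
want a fully simulated screen with known ground truth to test scoring and
network-inference machinery against.

Under the multiplicative null, two functionally unrelated mutations
combine as the product of their single-mutant fitnesses,
*W<sub>qr</sub>* = *W<sub>q</sub>* · *W<sub>r</sub>*. The epistasis
S-score measures the deviation of the observed double-mutant growth from
that expectation, scaled by a floored standard error:

    S = (mean(observed) − expected) / sqrt(max(s², s²_floor) / n)

High-confidence interactions are the pairs with |S| ≥ 3 (about two robust
standard deviations of the score distribution): S ≤ −3 aggravating
(synthetic sick/lethal), S ≥ +3 alleviating. From the signed network the
package computes topology (degrees, clustering, betweenness, hubs,
essential-gene centrality), monochromaticity of bioprocess pairs
(M = (n<sub>all</sub> − n<sub>agg</sub>)/(n<sub>all</sub> + n<sub>agg</sub>),
−1 purely aggravating … +1 purely alleviating), GI-profile correlation
with KS-based class contrasts and precision–recall cutoff selection,
permutation-based module crosstalk (Z ≥ 2.5), and co-conservation of gene
pairs by mutual information over binary phylogenetic profiles across a
233-genome panel (MI ≥ 0.2, PCC ≥ 0.5 cliques).

A first-class simulator (`screen_config()`, `generate_ground_truth()`,
`simulate_plates()`, `generate_phylo_profiles()`) generates complete
screens — plate gradients, batch wobble, replicate-plating effects,
linkage suppression, planted epistasis concentrated in coupled functional
modules, module-correlated ortholog profiles — so every downstream stage
is testable without any external download.

## Worked example

```r
library(giscreen)

cfg    <- screen_config(n_queries = 20, n_recipients = 400, rng_seed = 20)
truth  <- generate_ground_truth(cfg)
screen <- simulate_plates(truth, cfg)

norm   <- normalize_plates(screen)
scores <- score_screens(norm)
coords <- setNames(truth$genes$coordinate, truth$genes$gene)
scores <- mask_linked(scores, coords, window_bp = 30000,
                      chromosome_length_bp = 4641652)
net    <- threshold_network(scores, s_cut = 3)
print(net)
#> gi_network: 400 nodes, 284 edges (149 aggravating, 135 alleviating)

counts <- process_pair_counts(net, truth$genes)
enr    <- pair_enrichment(counts, net, truth$genes)
head(enr[order(enr$p), c("process_a", "process_b", "n_aggravating",
                         "n_alleviating", "M", "p")], 5)
#>    process_a process_b n_aggravating n_alleviating          M            p
#> 12       P03       P03             6            13  0.3684211 9.156615e-09
#> 7        P01       P07            13            12 -0.0400000 7.429348e-06
#> 14       P03       P05             8            10  0.1111111 6.402592e-05
#> 13       P03       P04             7            12  0.2631579 2.634850e-04
#> 2        P01       P02            20             1 -0.9047619 3.350857e-04
```

The screen thresholds into a signed network of 284 interactions. The
process-pair table shows where interactions concentrate and how sign-pure
they are: the P01–P02 pair carries 20 aggravating against 1 alleviating
interaction (M = −0.90, near the purely aggravating anchor of −1), while
P03's internal wiring leans alleviating (M = +0.37). On this simulated
screen those enrichments recover the module couplings the generator
planted; on a real screen the same table is read as functional crosstalk
between bioprocesses.

The numbered drivers under `analysis/` run the complete study on this
simulated screen — `01_simulate.R` through `07_conservation.R` — each
stage re-runnable from the plain-text files the previous stage wrote under
`results/`. On the default run they report, among other things,
replicate-screen reproducibility r = 0.883, recipient single-mutant
fitness recovered within 5% for 97.8% of genes, 97.2% of strongly planted
interactions re-called with the correct sign, and the planted module
structure recovered as co-conserved, correlated clusters.

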