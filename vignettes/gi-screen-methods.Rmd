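---
title: "Scoring and interpreting bacterial genetic-interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and interpreting bacterial genetic-interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Conjugation-based synthetic genetic array screening in *E. coli* (eSGA)
crosses a set of query donor mutations into an arrayed, genome-wide
collection of recipient mutants (deletions for non-essential genes,
hypomorphic alleles for essential ones) and reads out double-mutant fitness
as colony size on dense agar plates. A genetic interaction is a deviation
of the double mutant's fitness from the *multiplicative* expectation of its
two single mutants:

$$ W_{qr} \neq W_q \cdot W_r $$

Negative deviations (aggravating, synthetic sick/lethal) suggest redundant
or parallel functions; positive deviations (alleviating) suggest shared
pathways or complexes. `giscreen` implements the full analysis chain —
screen simulation with known ground truth, plate normalization, S-score
epistasis calling, signed-network topology, monochromaticity of bioprocess
pairs, GI-profile correlation and benchmarking, permutation-based module
crosstalk, and phylogenetic-profile mutual-information co-conservation —
as an R package with plain-text file interfaces, driven end to end by the
numbered scripts under `analysis/`.

# The synthetic screen generator

Everything downstream is validated against simulated screens whose truth is
known. The generator emulates the geometry of a genome-scale screen:
163 queries by default, a 4,117-strain recipient array with a small
hypomorph fraction, 384-colony plates with each strain at two duplicate
positions, and two replicate screens pinned as two plate copies each, so
every pair is measured eight times. A colony's size is

$$ s = P \cdot R_{row} \cdot C_{col} \cdot f_q \cdot f_r \cdot (1+\varepsilon_{qr})
       \cdot \ell_{qr} \cdot b_{strain,copy} \cdot e^{\eta} $$

with plate scale $P$ (lognormal batch wobble, $\sigma = 0.10$), smooth
sinusoidal row/column gradients (amplitude 0.08) plus an additive edge
boost (0.15) mimicking nutrient edge effects, single-mutant fitness
$f_q, f_r$, the planted epistasis deviation $\varepsilon$, linkage
suppression $\ell = 0.05$ for loci within 30 kb on the circular chromosome,
a per-plate-copy per-strain plating effect $b$ (lognormal,
$\sigma = 0.12$), and per-colony lognormal noise $\eta$
($\sigma = 0.15$). Noise is multiplicative throughout because colony sizes
are positive and right-skewed.

Choices worth flagging:

* **Fitness distribution.** Most deletion strains carry no measurable
  defect on rich medium, so 60% of deletions sit exactly at fitness 1 and
  the rest are uniform on [0.2, 1]; hypomorphs are uniform on [0.5, 0.9]
  (viable partial-function alleles of essential genes). A no-defect modal
  class is both realistic for rich-medium deletion collections and what
  anchors median/mode-based normalization.
* **Plating effect.** The duplicate colonies of a strain on one plate copy
  are pinned from the same source position and share their conjugation and
  outgrowth history. The per-copy, per-strain effect ($\sigma = 0.12$)
  models that shared biological variation; it is what limits
  replicate-screen reproducibility to $r \approx 0.88$ on the default
  configuration, in the realistic range for high-quality screens. Without
  it, simulated replicates correlate at $r \approx 0.95$, which no real
  screen achieves.
* **Planted interactions.** Each tested pair is aggravating with overall
  probability 0.02 and alleviating with 0.015. Deviations are uniform on
  $\pm[0.3, 0.9]$ — the magnitude distribution of real epistasis is
  unknown, so this is an explicit free choice, configurable in
  `screen_config()`. Half-ish of planted pairs are routed through
  *coupled module pairs* (planting probability 0.4 inside a coupling, with
  a fixed sign per coupling), so module-level monochromaticity, crosstalk
  and profile-correlation structure are recoverable downstream. Essential
  (hypomorph-built) modules are self-coupled aggravating; non-operonic
  non-essential query modules are self-coupled alleviating — the planted
  analog of essential complexes being aggravating-biased.
* **Layouts** distribute recipients near-evenly over plates. A sequential
  fill leaves the last plate nearly empty, and a plate's scale can only be
  anchored against its own resident strain-fitness distribution (see
  below), which needs a reasonable number of strains.
* **Phylogenetic profiles** give each module a latent presence pattern over
  233 genomes in three relatedness groups (29 serotypes, 64 enterobacteria,
  140 gamma-proteobacteria); member genes copy it with probability 0.9.
  Retention decays with phylogenetic distance through group exponents
  `retention^alpha`, alpha = (0.25, 1, 2), so close relatives retain more.

What the generator does *not* emulate: conjugation chemistry and marker
selection, image segmentation artifacts, position-dependent pinning
failures, batch-to-batch layout changes, suppressor sweeps, or any
correlation between a gene's fitness and its interaction degree. Passing
tests therefore certify the statistical machinery under a faithful noise
and design model, not performance on any particular real dataset.

# Normalization

All corrections are multiplicative:

1. **Plate scale.** Every plate's median (occupied, non-zero colonies) is
   scaled to the experiment-wide median. This absorbs batch effects and the
   query single-mutant growth rate — so in normalized space the
   multiplicative expectation for a pair is `scale * f_recipient` with the
   query factor already removed.
2. **Spatial gradients.** Row and column factors (which include the edge
   boost) are estimated by an alternating robust fit in log space:
   strain effects given spatial factors, spatial factors given strain
   effects (20%-trimmed means, eight sweeps), pooled across all plate
   instances of the same layout plate. Two details matter on a *fixed*
   layout. First, a per-plate median polish confounds a row's strain
   composition with its spatial factor — a row that happens to carry sick
   strains looks like a slow-growth region, and because the layout never
   changes, the error never averages out (we measured 6–10% bias on sick
   strains). Computing factors on strain-corrected residuals and pooling
   across instances removes this. Second, a strain's own median absorbs
   the spatial effect at its fixed positions, so naive residual factors are
   attenuated; the alternation converges to the joint fit instead.
3. **Plate anchoring.** A strain never changes plates, so layout-plate
   scale and strain fitness are exactly confounded. Each layout plate is
   anchored at the *mode* of its resident per-strain median sizes — the
   assumption being that every plate's modal strain has no defect. This is
   why the generator's no-defect modal class matters; for arrays of mostly
   sick strains the anchor assumption would fail and an external reference
   (border control strains) would be needed.

Plates with more than 50% dead (zero) colonies among occupied positions are
rejected with a warning (configurable). Zero colonies never enter any
estimate.

# Fitness estimation and S-scores

Recipient fitness is the strain's trimmed log-mean normalized size over the
modal strain size. Gross low outliers (more than 3.5 robust SD below the
strain's own median) are rejected first: linkage-suppressed and strongly
aggravated colonies otherwise leak past any fixed trim fraction when a
strain happens to lie near several query loci. Scoring then iterates
twice: score, exclude pairs at `|S| >= 2.5` from the fitness estimate,
re-score — so genuine interactions do not contaminate the single-mutant
baseline they are measured against. Query fitness is reported from
pre-scaling plate medians relative to the replicate batch median, but it is
a nuisance scale: plate normalization removes it from the data, so it plays
no role in scoring, and parameter-recovery statements are about recipient
(array) genes.

The S-score for a pair is a one-sample t-style statistic

$$ S = \frac{\bar{x} - \mu}{\sqrt{\max(s^2, s^2_{floor}) / n}} $$

with three implementation decisions:

* **Measurement units are plate-copy means** of the duplicate colonies
  ($n = 4$ independent units per pair at the default design), because
  duplicates share a pinning source; treating all 8 colonies as
  independent understates the standard error and inflates false calls.
* **The variance floor is relative**: the experiment-wide median of
  `var/expected^2`, times the pair's squared expectation. Noise is
  multiplicative, so an absolute floor (the median within-pair variance)
  over-floors low-fitness pairs — we measured a ~10% sensitivity loss for
  planted interactions on sick recipients before switching.
* **The expectation scale is calibrated** as the median over pairs of
  `mean(observed) / f_recipient`, which centers the null S distribution
  (under lognormal noise the mean of a pair exceeds its median-based
  expectation by $e^{\sigma^2/2}$).

`Z` standardizes S against the robust core (median/MAD) of the score
distribution: genuine interactions live in the tails and would inflate a
moment-based SD. On default simulations the null S distribution is centered
(|mean| < 0.05), symmetric, has MAD near 0.95, and puts less than 1% of
pairs beyond |S| = 3 — so the |S| >= 3 network threshold sits beyond two
robust SD, the conventional two-standard-deviation outlier criterion.

Pairs of loci within 30 kb (circular distance) are masked as linked before
thresholding: double-mutant recovery between closely linked markers is
suppressed by reduced recombination, not by epistasis. The window is
configurable; 30 kb is a deliberately generous default for a ~4.6 Mb
chromosome. When both orientations of a pair were screened, the more
extreme |S| wins (no published rule exists; max-|S| keeps the
better-powered measurement).

# Downstream statistics

* **Topology** (`gi_topology`): average clustering coefficient is the
  Watts–Strogatz mean of local coefficients with degree-<2 nodes
  contributing 0; betweenness is normalized shortest-path betweenness on
  the unsigned graph; hubs are nodes at or above a total-degree threshold
  (640 at genome scale; scale it down for desk-size screens). Essentiality
  contrasts use two-sided rank-sum tests; the within-complex
  aggravating/alleviating balance is a two-sided Fisher exact test, with a
  complex called essential when at least half its members are.
* **Monochromaticity**: for each unordered pair of bioprocess labels
  (self-pairs included — within-process purity is needed for module work),
  signed counts of spanning edges, the score
  $M = (n_{all} - n_{agg}) / (n_{all} + n_{agg})$ anchored at −1 (purely
  aggravating) and +1 (purely alleviating), and a hypergeometric
  enrichment p with the pairs of annotated tested genes as the urn.
  Because the published protocol for the enrichment null is not public,
  a label-permutation alternative is built in; per-sign and any-sign p
  values are both reported, with BH q-values across pairs.
* **Module crosstalk** (`permutation_enrichment`): intra- and inter-module
  signed counts (genes shared by a module pair are excluded from that
  pair's inter count), a null built by permuting gene-to-module assignment
  (preserving module sizes and each gene's membership count), Z-scores and
  add-one empirical p per sign, and the significance conjunction
  Z >= 2.5, p <= 0.05, and >= 3 interactions for inter-module pairs (the
  edge floor is not applied to intra-module tests). Degree-preserving edge
  rewiring is available as an alternative null; note the two nulls answer
  slightly different questions for intra-module counts, since rewiring
  conditions on degrees.
* **Profiles**: a gene's GI profile is its row of S-scores across queries.
  Correlations are pairwise-complete over unmasked cells with a minimum
  overlap (default 20 shared queries; lower it for short profile axes).
  Class contrasts (co-complex vs size-matched random pairs, operon
  first/last vs first/middle) use two-sample KS tests; `ks.test` computes
  exact p for small untied samples and the asymptotic p otherwise.
  Literature overlap uses a uniform random-pair null over screened genes
  (degree-matched endpoints optional) and the add-one permutation p, which
  never reports zero.
* **Co-conservation**: plug-in mutual information in bits over binary
  ortholog profiles, no bias correction — profiles are length 233 and the
  conventional 0.2 cutoff is on the plug-in scale; a joint-entropy
  normalized variant sits behind a flag. Clusters are connected components
  of the graph of pairs passing both `MI >= 0.2` and `r >= 0.5`, with
  maximal cliques enumerated inside components of at most 25 genes;
  co-conserved but anti-correlated pairs (`r <= -0.5`) are flagged
  separately.

# Problem sizes, tolerances, numerical notes

The bundled analyses and tests run the generator at 20 queries x 400
recipients (92,160 colonies) — the scale at which parameter recovery is
assessed: >= 90% correct sign calls for planted |deviation| >= 0.5,
recipient fitness within 5% for >= 95% of genes, replicate correlation in
[0.6, 0.9]. The large-sample sensitivity property uses 40 x 800 (over 500
strong planted pairs); permutation calibration checks use 500 null trials
with 199 permutations each. Exact statistics are verified against
brute-force enumeration: Fisher and hypergeometric to 1e-10, KS D and
plug-in MI to 1e-12. Degenerate inputs are defined, not crashed: both-zero
monochromatic counts and sub-minimum replication raise typed errors; empty
curated sets, unknown groups and malformed files fail with messages naming
the file, line and field; a constant profile has zero MI and an undefined
correlation.

At desk scale the precision-recall-selected profile-correlation cutoff
lands near 0.75 rather than the 0.3 used for genome-scale profiles: with
only 20 queries, profile correlation noise (sd about $1/\sqrt{20}$) pushes
any useful precision target to higher cutoffs. The selection machinery,
not the specific cutoff value, is the transferable piece.

# Known limitations

The generator's separable row/column spatial model is kinder than real
plate artifacts (local blobs, pinning dropouts); the normalization's
pooled factors would average over per-plate deviations it does not model.
The plate-anchor assumption (modal resident strain has no defect) fails
for arrays dominated by sick strains. Query single-mutant fitness is not
recoverable from plate-normalized data by design. The monochromaticity
enrichment urn treats gene pairs as exchangeable, ignoring degree
structure — the permutation alternative and the rewiring null exist for
exactly that worry. MI on 233 genomes retains the plug-in estimator's
small positive bias (about 0.01–0.02 bits for independent balanced
profiles), which the 0.2 cutoff dwarfs.
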