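Package: giscreen
Title: Genetic-Interaction Screen Simulation, Epistasis Scoring and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for conjugation-based genome-wide genetic-interaction
    (eSGA-style) screens in bacteria: simulation of colony-array screens with
    known ground truth, plate normalization, multiplicative-model epistasis
    (S-score) scoring with linkage masking, signed interaction-network
    topology, monochromaticity of bioprocess pairs, genetic-interaction
    profile correlation with benchmarking against curated standards,
    permutation-based module crosstalk enrichment, and phylogenetic-profile
    mutual-information co-conservation analysis. Includes plain-text
    readers and writers for every intermediate format so each stage is
    re-runnable from its on-disk inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
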