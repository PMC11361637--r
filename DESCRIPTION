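Package: fatescreen
Title: Fate-Biased Retinal Regeneration: Simulation, Trajectory Deltas,
    Signed Gene-Regulatory Networks and Crispant Screen Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fate-biased retinal regeneration from
    single-cell transcriptomics and fluorescence plate-reader screens.
    Simulates Muller-glia-to-progenitor-to-neuron trajectories with a
    planted signed transcription-factor network and negative-binomial
    counts; provides quality control, rank-sum marker/DEG testing,
    principal-curve pseudotime with 50-bin per-condition delta profiles,
    tree-ensemble gene-regulatory-network inference with quantile and
    correlation-sign filtering, hypergeometric cell-type specificity
    scores for transcription factors, and crispant screen statistics
    (power-based design, per-gene ANOVA and the Benjamini-Krieger-
    Yekutieli two-stage false-discovery-rate procedure with hit
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
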