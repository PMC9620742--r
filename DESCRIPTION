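Package: lever2p
Title: Analysis of Layer-5 Two-Photon Calcium Imaging During a Push/Pull Lever Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-structured analysis of two-photon calcium imaging (and spiking)
    population recordings from motor cortex during a cued push/pull forelimb lever
    task. Provides a ground-truth synthetic session generator; motion-index and
    dF/F0 signal preparation with motion-index onset detection; bootstrap
    classification of neurons into movement-related, reward-phase and
    non-responsive groups with movement-invariant versus push/pull-biased
    subtypes; slope-sum-function response-onset detection with simulation-based
    calibration; single-neuron leave-one-out Gaussian naive-Bayes decoding of
    movement type with a simulated-null significance threshold and population
    logistic-regression decoding with neuron-removal analyses; PCA trajectory
    separability (d-prime) with trial-shuffle significance; and spatiotemporal
    statistics of pairwise correlations and distances including a REML
    mixed-model test of spatial clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    signal,
    lme4,
    lmerTest,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
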