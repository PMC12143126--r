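Package: aebnet
Title: Directed Theta-Band Network Analysis for Action-Effect Binding EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying directed theta-band network
    communication during action-effect binding from frequency-tagged EEG.
    Provides a synthetic-data generator with known directed-coupling ground
    truth (trial timelines, SSVEP frequency tagging, coupled source dynamics,
    a toy leadfield), BrainVision input/output and basic preprocessing
    (resampling, band-pass, epoching), Morlet time-frequency decomposition
    with baseline-relative power and pointwise paired contrasts under FDR
    control, DICS source localization with DBSCAN region-of-interest
    extraction and LCMV virtual sensors, a neural-network nonlinear
    multivariate autoregressive estimator of directed linear and nonlinear
    connectivity via Taylor decomposition, circular time-shift surrogate
    significance testing, and a paired t / FDR / Cohen's d / JZS Bayes factor
    inference layer producing a publication-style connectivity report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
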