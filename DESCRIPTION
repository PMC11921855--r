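Package: clpnet
Title: Cross-Lagged Panel Network Analysis of Two-Wave Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and stability analysis of cross-lagged panel networks
    (CLPNs) from two-wave ordinal symptom panels such as the PHQ-9. Provides
    cutoff-based depressive-trajectory stratification (chronic, delayed,
    recovery, resistance), per-group node-wise LASSO temporal network
    estimation with 10-fold cross-validated penalty selection, expected
    influence centrality (in-EI and out-EI in overall, cross-lagged and
    cross-construct variants), nonparametric bootstrap edge-weight confidence
    intervals, case-drop correlation-stability (CS) coefficients, edge and
    centrality difference tests, between-group network-structure correlations,
    a latent-threshold synthetic panel generator with trajectory-scenario
    presets, and a pipeline orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
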