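Package: chemodyn
Title: Long-Term Chemotherapy Response Dynamics in Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying long-term drug response dynamics in
    longitudinally monitored cancer cell populations. Implements a family of
    two-compartment resistant/sensitive ordinary differential equation growth
    models with delayed drug-induced death and delayed regrowth, simulation of
    realistic synthetic plate data, preprocessing of raw cell-count series
    (truncation and media-handling discontinuity normalization), bounded
    multi-start nonlinear least-squares calibration, AIC-based model selection,
    simulation-based parameter identifiability analysis, density-clustering
    detection of the proliferation delay from nuclei centroids, leave-one-out
    predictive validation, and treatment-schedule performance metrics
    (non-recovering fraction and critical-time projections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
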