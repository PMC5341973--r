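Package: synergyscreen
Title: Drug Combination Screen Analysis with Bliss Scores and Combination
    Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-throughput drug-combination
    viability screens on patient-derived cancer cell cultures. Normalizes
    raw plate fluorescence against vehicle controls, fits four-parameter
    log-logistic dose-response curves, quantifies drug-drug interaction by
    Bliss interaction scores (with label-permutation significance) and by
    fixed-ratio Chou-Talalay combination indices averaged over the 40-60%
    effect band, and summarizes synergy across a cohort with Wilcoxon
    signed-rank statistics. Includes elastic-net prediction of per-culture
    synergy from molecular profiles with leave-one-out tuning and feature
    selection frequencies, DNA-content cell-cycle gating with per-culture
    regressions and a common-slope linear mixed-effects model, factorial
    knockdown/drug interaction models, and seeded synthetic-data generators
    with known ground truth emulating a 41-culture glioma screen.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
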