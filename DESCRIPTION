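Package: permsplit
Title: Permutation-Based Split-Half Reliability for Reaction-Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-session reliability estimation for trial-level
    reaction-time tasks such as the approach-avoidance task. Implements
    stratified permutation-based split-half reliability with Olkin-Pratt
    aggregation of split correlations and a mirrored Spearman-Brown
    length correction, alongside the estimators it is commonly compared
    against (Cronbach's alpha on stimulus subscores combined with Lord's
    difference-score formula, odd-even and first-second split-half, and
    the Monte Carlo split-half). Includes a hierarchical-normal
    synthetic-data generator with closed-form true reliabilities and
    simulation harnesses that evaluate estimator accuracy, the number of
    splits required for a stable estimate, and the calibration of
    permutation-based confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
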