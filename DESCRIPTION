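Package: rbvidh
Title: Relative Blood Volume Dynamics and Intradialytic Hypotension Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous relative blood volume (RBV)
    monitoring during hemodialysis in relation to intradialytic hypotension
    (IDH): RBV computation from hematocrit, IDH event labelling, dynamic
    time warping (DTW) clustering of session trajectories into risk groups,
    a time-dependent Youden-index RBV threshold with LOESS smoothing and
    bootstrap bands, mixed-effects logistic models (patient random
    intercept) for concurrent and 10-60 minute predictive risk, session-wise
    and patient-wise validation, and a calibrated synthetic-cohort simulator
    so every stage is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    cluster,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
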