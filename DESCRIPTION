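Package: microalb
Title: Predicting Microalbuminuria from Proteinuria in Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating the urinary protein-to-creatinine ratio (uPCR)
    to the urinary albumin-to-creatinine ratio (uACR) in adults with
    lifestyle-related chronic kidney disease. Implements repeated-measurement
    albuminuria classification, KDIGO GFR categorisation and cohort
    eligibility filtering, binned-median summaries with piecewise log-linear
    and restricted cubic spline calibration of median uACR on uPCR (knot
    placement at standard percentiles, AIC knot-count selection, slope-change
    inference, forward and inverse prediction), empirical ROC machinery with
    Youden-index cutoffs and DeLong comparison of correlated AUCs, an
    intra/interday sample-stability analysis, and seeded synthetic cohort and
    stability-study generators so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    readr,
    ggplot2
Config/testthat/edition: 3
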