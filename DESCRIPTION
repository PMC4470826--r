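Package: egfragree
Title: Method Comparison of GFR Estimating Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing creatinine- and cystatin-C-based estimates of
    the glomerular filtration rate (GFR) in adult cohorts. Implements the
    Cockcroft-Gault, MDRD-4, CKD-EPI creatinine, van Deventer and CKD-EPI
    cystatin C equations with explicit black-American factor variants;
    Bland-Altman agreement analysis with mean-difference and limits-of-agreement
    lines modelled as functions of the pairwise mean (classic, linear-regression
    and quantile-regression constructions, robust to heteroscedasticity); bias,
    precision, relative bias and P10/P30 accuracy concordance summaries; CKD
    stage cross-classification and dichotomized discrepancy counts; cohort file
    import with unit conversion and descriptive statistics; and a
    log-normal-copula synthetic cohort generator calibrated to a Malawian adult
    study population, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    quantreg,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
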