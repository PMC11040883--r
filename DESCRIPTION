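Package: champr
Title: Missingness-Adaptive 30-Day Mortality Prediction for Physician-Staffed
    HEMS Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and internal validation of CHAMP-style mortality
    prediction algorithms for pre-hospital critical care cohorts. Provides
    variable screening against missingness and prevalence cut-offs, multiple
    imputation by chained equations with predictive mean matching, winsorized
    restricted-cubic-spline logistic modelling pooled by Rubin's rules, a
    32-submodel pattern ensemble that scores each patient with the model
    using the most available predictors, discrimination and calibration
    metrics (AUROC, Brier, calibration slope and intercept,
    Hosmer-Lemeshow), bootstrap optimism correction on multiply imputed data,
    and a synthetic cohort generator calibrated to a national HEMS registry's
    published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nnet,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
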