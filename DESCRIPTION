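Package: patternrisk
Title: Pattern-Tailored Clinical Risk Prediction with Systematically Missing
    Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates logistic-regression risk prediction models
    from multiple heterogeneous cohorts in which some centres never collect
    some risk factors and individual patients miss others. Six missing-data
    accommodation strategies (available cases, iterative BIC selection,
    cohort ensemble, categorization, missing indicator, multiple imputation
    by chained equations) share one fit/predict interface tailored to the
    set of predictors a query patient actually supplies. Includes a
    per-pattern submodel library for deployment, calibration-in-the-large,
    AUC with DeLong confidence intervals, decile calibration curves,
    external and leave-one-cohort-out validation, and a synthetic
    multi-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
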