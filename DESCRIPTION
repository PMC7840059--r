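Package: gpospom
Title: Table-Driven POSPOM Scoring and Validation for Coded Hospital Case Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Preoperative Score to Predict Postoperative
    Mortality (POSPOM) from case-level administrative hospital records coded
    with ICD-10 diagnoses and OPS procedures, applies the eligibility cascade
    used in registry-based validation studies (index procedure, adult age,
    complete record) with full attrition accounting, and evaluates prognostic
    performance against in-hospital death via ROC c-statistic, Brier score,
    Wald confidence intervals, per-score mortality and calibration plots.
    Point tables are user-supplied configuration; a synthetic-registry
    generator with a configurable score distribution and logistic outcome
    link allows the whole pipeline to run without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
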