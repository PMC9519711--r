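Package: csdhvalid
Title: External Validation of Prognostic Models for Chronic Subdural
    Hematoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the external validation of published prognostic
    risk scores and nomograms for chronic subdural hematoma (CSDH).
    Published models are loaded from structured definition files and
    evaluated on patient-level cohorts to obtain predicted probabilities;
    performance is quantified by calibration-in-the-large, calibration
    intercept and slope (offset logistic regression), the concordance
    index with bootstrap confidence intervals, and the model-based
    concordance that isolates case-mix heterogeneity.  Missing predictor
    values are handled by multiple imputation with chained equations
    (predictive mean matching, logistic and multinomial conditionals)
    and validation statistics are pooled across imputations with Rubin's
    rules.  A synthetic cohort generator reproduces registry-style
    marginal distributions, configurable true outcome models, and
    region-structured missingness so the whole pipeline can be exercised
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
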