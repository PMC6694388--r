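Package: payrisk
Title: Claims-Based Payment Risk Models with Present-on-Admission and
    Individual-Code Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares claims-based models of 30-day episode
    payments for condition cohorts (acute myocardial infarction, heart
    failure, pneumonia). Constructs candidate risk variables under seven
    schemes spanning grouped hierarchical condition categories and
    individual diagnosis codes, with present-on-admission logic and
    separation of index-admission from 12-month-history diagnoses; fits
    Gamma and inverse-Gaussian generalized linear models with penalized
    (LASSO) variable selection under a variable-count cap and a
    significance constraint; compares models by McFadden pseudo R-squared,
    cross-validated RMSE and decile predictive ratios; and profiles
    hospitals by risk-standardized payment from a hierarchical GLM with
    cluster-bootstrap confidence intervals and three-way categorization
    against the national mean. A synthetic claims generator with recorded
    ground truth supports end-to-end testing and parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
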