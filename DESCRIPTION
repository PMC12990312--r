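Package: pvfaers
Title: Disproportionality Signal Detection and Drug Screening for
    FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous
    adverse-event report databases in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII layout. Parses and deduplicates
    report tables, builds per-drug 2x2 contingency tables for a target
    MedDRA preferred term, and computes four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    chi-square, the Bayesian confidence propagation neural network
    information component, and the multi-item gamma Poisson shrinker
    empirical-Bayes geometric mean) with per-method and consensus signal
    flags. Also implements a drug-screening cascade (univariate logistic
    screen, LASSO selection with cross-validation, covariate-adjusted
    multivariate logistic regression with ROC/AUC), time-to-onset
    summaries, and a synthetic FAERS-style data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
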