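Package: mcitransfer
Title: Cross-Cohort Transfer of Penalized MRI-Feature Classifiers for
    MCI Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how well penalized logistic classifiers
    trained on multiparametric MRI feature tables from a clinical
    Alzheimer's disease cohort transfer to mild-cognitive-impairment
    detection in a population-based cohort scanned on different
    hardware. Provides a two-cohort synthetic feature-table generator
    with a disease-severity continuum, scanner and covariate effects;
    per-feature affine center correction estimated on repeated balanced
    control subsets; elastic-net logistic models with unpenalized
    age/sex covariates and repeated nested 10-fold cross-validation;
    ROC/AUC machinery with optimal operating points; and the full
    inferential battery (paired bootstrap AUC comparison, max-statistic
    permutation tests against chance, rank-sum score contrasts, and
    permutation tests on score overlap with Bonferroni adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
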