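Package: addmetrics
Title: Analytically Derived Distributions for Classification Model Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to summarise the sampling distribution of binary-classifier
    evaluation metrics (AUROC, accuracy, F1, sensitivity, specificity, PPV,
    NPV, balanced accuracy) and tree-ensemble feature-importance gain.
    Implements analytically derived Gaussian distributions (ADD) from
    Mann-Whitney and binomial-proportion variance formulas, a Monte-Carlo
    train/test re-splitting engine with pluggable model adapters, an
    Anderson-Darling check of whether mean and SD are sufficient summaries,
    a synthetic heart-disease-like cohort generator with a known logistic
    signal, and comparison tables of analytic versus resampled distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    randomForest,
    nortest,
    grDevices
Config/testthat/edition: 3
RoxygenNote: 7.3.3
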