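Package: mixqspr
Title: QSPR Modeling of Non-Additive Binary Mixture Properties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative structure-property modeling of binary
    liquid mixtures whose properties are not additive in their components.
    Provides a canonical mixture data model (majority-component-first storage,
    duplicate detection, pure-compound augmentation), four mixture-descriptor
    schemes built from single-compound descriptors (average, sum plus absolute
    difference, mole-fraction-weighted sum, and weighted sum plus weighted
    absolute difference), leakage-safe external validation protocols
    ("points out", "mixtures out", "compounds out") with a brute-force audit,
    pluggable per-compound descriptor backends and estimators, evaluation
    metrics (R2, RMSE, Q2, balanced accuracy, per-class recall), and a seeded
    synthetic-data generator for concentration-dependent regression endpoints
    and azeotrope/zeotrope classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    FNN,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
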