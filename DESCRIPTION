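Package: antioxpep
Title: Antioxidant Peptide Classification from Sequence-Derived Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting antioxidant activity of short peptides from
    their primary sequence. Implements four descriptor encoders (averaged
    AAindex physicochemical properties, composition/transition/distribution
    over 13 property partitions, adaptive skip dipeptide composition, and
    frequency-weighted BLOSUM62 substitution profiles), enumeration and
    fusion of descriptor combinations, gradient-boosted split-count feature
    ranking with nested top-k sweeps, a six-algorithm shallow classifier
    harness culminating in a radial-kernel support vector machine, a
    seven-metric evaluation suite with stratified cross-validation and the
    Friedman rank test, two-dimensional feature-space embeddings, and a
    synthetic labeled-peptide generator so the whole pipeline can be
    exercised without external data. A command-line interface exposes the
    pipeline stages as composable subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
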