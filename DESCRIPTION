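Package: dtiforest
Title: Drug-Target Interaction Prediction from Evolutionary Profiles and
    Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feature-based pipeline for predicting drug-target interactions
    (DTIs). Proteins are described by pseudo position-specific scoring matrix
    (PsePSSM) descriptors and detrended cross-correlation analysis (DCCA)
    coefficients computed from PSI-BLAST evolutionary profiles; drugs by
    256-dimensional nibble encodings of 1024-bit FP2 path fingerprints. Pair
    feature tables are reduced by L1 (Lasso) feature selection, rebalanced by
    SMOTE oversampling with majority undersampling, and classified by a random
    forest. Includes five-fold cross-validated evaluation with ROC/PR curves,
    parameter scans for the PsePSSM lag and DCCA segment length, ranked
    inference of novel interactions, and a seeded synthetic-data generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
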