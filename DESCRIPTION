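Package: entrofuse
Title: Multiple-Entropy Fusion Analysis of EEG for Driver Fatigue Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for detecting
    driver fatigue from multichannel EEG. Computes spectral, approximate,
    sample and fuzzy entropy per channel and epoch, fuses them by
    concatenation with per-subject min-max normalization, and compares the
    fused features against Yule-Walker autoregressive coefficients using
    four classifiers (RBF support vector machine, feedforward network,
    random forest, nearest neighbour) under leave-one-out cross-validation.
    Includes an accuracy-weight electrode-selection statistic for ranking
    scalp channels, a synthetic two-state EEG cohort generator for method
    evaluation, and plain-text readers and writers for recordings, feature
    tables and evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
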