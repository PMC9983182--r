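Package: augsplit
Title: Placement of Data Augmentation Relative to Dataset Splitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for studying where geometric data
    augmentation is applied relative to the division of an image-classification
    dataset into training, validation and test subsets. Provides a synthetic
    two-class image generator with rotation/flip-invariant class signal and
    per-image identity fingerprints, eight-fold dihedral (flip/rotation)
    augmentation with full provenance tracking, stratified k-fold
    cross-validation and 3:1 train/validation splitting under the eleven
    augmentation-placement protocols, information-leakage auditing, a
    mini-batch training harness with validation-gated early stopping, and
    pooled cross-validation statistics: micro-averaged accuracy, sensitivity
    and specificity with Clopper-Pearson exact binomial confidence intervals,
    pooled ROC AUC, t-based confidence intervals for epoch counts and training
    times, and the correlation of performance metrics with log training time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
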