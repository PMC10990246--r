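Package: wsosvm
Title: Weakly Supervised Ordinal Support Vector Machines for Mapping
    Intra-Tumoral Genetic Heterogeneity from Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Trains a three-source ordinal kernel classifier that combines
    labeled biopsy samples (gene non-altered vs altered), unlabeled tumoral
    samples known only to be tumor, and normal-brain samples, by solving the
    convex dual quadratic program of the weakly supervised ordinal support
    vector machine (WSO-SVM).  Includes window-based radiomic feature
    extraction (statistical, gray-level co-occurrence matrix and Gabor
    texture features over five MRI contrasts), repeated stratified
    cross-validation with two-stage hyperparameter tuning, Shapley-value
    attribution aggregated to the MRI-contrast level, stride-1
    sliding-window regional prediction maps, and a synthetic cohort
    generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
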