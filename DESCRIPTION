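Package: drivewave
Title: EEG Spectral Biomarkers and Neurological State Classification for
    Driving Workload Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying driving-induced mental workload from
    low-density (prefrontal/occipital) EEG. Provides a calibrated synthetic
    multichannel EEG generator, artifact injection and removal (notch,
    anti-aliased downsampling, zero-phase band-pass, reference-guided
    FastICA), Welch power spectral density estimation, band relative powers
    and spectral summary frequencies, composite biomarkers (delta-alpha and
    delta-theta ratios, frontal asymmetry, baseline-relative change), the
    149-feature epoch table, descriptive and paired-comparison statistics,
    ANOVA F-test feature selection, and class-imbalance-aware cross-validated
    classification (KNN, linear discriminant, RBF-SVM, gain-ratio tree,
    univariate-split tree) with confusion-matrix/ROC/AUC/Gini reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    rpart,
    pracma,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
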