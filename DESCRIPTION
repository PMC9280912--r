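Package: ceustirads
Title: CEUS-TIRADS Scoring and Re-Grading of C-TIRADS 4 Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements an integer-weighted contrast-enhanced ultrasound
    (CEUS) diagnostic score for thyroid nodules of Chinese TIRADS
    (C-TIRADS) category 4, together with the CEUS-TIRADS combination rule
    that shifts the C-TIRADS category by at most one level according to
    the CEUS score and two benign overrides (absent enhancement and a
    peripheral hyper-enhancement ring). Provides the model-building
    statistics (Pearson chi-square screening, two-sample t-tests,
    multivariable logistic regression, odds-ratio based weight
    derivation), diagnostic-performance evaluation (sensitivity,
    specificity, accuracy, ROC/AUC with DeLong confidence intervals and
    paired DeLong comparison, Youden cutoff selection), cohort CSV
    input/output with validation, and a synthetic-cohort simulator plus a
    constraint-based fixture builder so that the whole pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
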