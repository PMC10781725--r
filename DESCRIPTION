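Package: psymeta
Title: Cross-Disorder Transcriptomic Meta-Analysis with Adaptively
    Weighted Fisher Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-study differential-expression meta-analysis pipeline
    for finding gene-expression signatures shared between two disease
    "databases" (collections of case/control studies), built for the
    setting where some studies report only truncated summary statistics.
    Provides per-study preprocessing (log2 decision rule, low-expression
    filtering, quantile normalization, duplicate resolution), empirical-
    Bayes moderated-t differential expression, cross-study direction
    concordance classification, adaptively weighted Fisher (AW-Fisher)
    p-value combination with censored-interval mean imputation for
    truncated tables, inverse-p-weighted log-fold-change pooling,
    hypergeometric over-representation analysis against GMT gene-set
    collections, leave-one-study-out cross-validated biomarker prediction
    with nested tuning (elastic net and random forest), and connectivity
    scoring of disease signatures against a perturbagen log-fold-change
    library to flag reversal candidates. A synthetic-data generator with
    planted shared and database-private differentially expressed genes
    exercises every stage offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
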