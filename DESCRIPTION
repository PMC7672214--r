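Package: taxarules
Title: Interpretable Multi-Class Classification of Microbial Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully deterministic workflow for classifying
    samples into many imbalanced classes (such as cancer types) from sparse
    microbial taxon abundance tables, and for explaining the classification
    with human-readable IF-THEN rules. Features are ranked by minimum
    redundancy / maximum relevance (mRMR) on three-state discretized
    abundances; nested top-k feature subsets are scored by incremental
    feature selection (IFS) under stratified 10-fold cross-validation with
    SMOTE oversampling applied inside training folds; performance is
    summarized by overall accuracy, per-class recall and the multiclass
    Matthews correlation coefficient; mutually exclusive classification
    rules are extracted from a CART decision tree grown on the optimum
    feature subset. A synthetic abundance-table generator with planted
    informative, redundant and noise taxa makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
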