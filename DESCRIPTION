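Package: hicreg
Title: Predicting Hi-C Contact Counts from One-Dimensional Regulatory Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A regression toolkit for predicting Hi-C chromatin contact
    counts between pairs of genomic bins from one-dimensional regulatory
    signals (chromatin marks, CTCF, DNase I accessibility and motif
    scores).  Random-forest models are trained on PAIR-CONCAT, WINDOW or
    MULTI-CELL feature encodings of region pairs with region-held-out
    cross-validation, cross-chromosome and cross-cell-line transfer, and
    ensemble averaging.  Downstream machinery covers distance-stratified
    correlation and its trapezoidal AUC summary, decision-path feature
    analysis with non-negative matrix factorization bi-clustering,
    multi-task group-lasso dataset selection with greedy random-forest
    refinement, binomial chromatin-loop calling with CTCF-orientation and
    ChIA-PET enrichment, directionality-index TAD detection, and a
    synthetic-data generator that emulates the full data regime for
    download-free testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
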