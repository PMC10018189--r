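Package: promforest
Title: Bacterial Promoter Prediction from Dinucleotide Physicochemical
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognising bacterial (Corynebacterium glutamicum
    style) promoters in fixed-length DNA windows. Sequences are encoded
    position by position through five statistical parameters (minimum,
    maximum, mean, variance, sum) of published dinucleotide physicochemical
    properties; redundant features are removed by pairing one-way ANOVA
    F values with first-level agglomerative clustering; a grid-searched
    random forest with Gini splits is trained under stratified five-fold
    cross-validation; and performance is reported as sensitivity,
    specificity, accuracy, Matthews correlation coefficient and the area
    under the ROC curve. A seeded simulator of property tables and
    motif-planted sequence sets makes the whole pipeline testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
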