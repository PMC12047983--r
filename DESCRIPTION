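Package: maskcover
Title: Variant Mask Construction, Burden Testing and Masking-Strategy
    Optimization for Rare-Variant Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining and harmonizing variant masks (boolean filters
    over functional annotations and allele-frequency thresholds), building
    composite pathogenicity scores from ensembles of predictor rank scores,
    running covariate-adjusted gene-level burden tests across allele-frequency
    bins with genomic-inflation calibration, clustering redundant masks, and
    selecting masking strategies that maximize the number of Bonferroni-
    corrected significant gene-trait associations via a greedy covering
    optimizer. Includes a synthetic-data generator with recorded ground truth
    for end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
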