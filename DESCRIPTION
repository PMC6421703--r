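Package: mgsea
Title: Multivariate Gene Set Enrichment Analysis via Conditional Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends rank-based gene set enrichment analysis to multimodal
    feature scores (for example copy-number, DNA methylation and mRNA
    expression scores for the same genes). Enrichment of a gene set in each
    platform, and in unions of platforms, is summarised by cumulative
    hit-count random walks over ranked gene lists; the contribution of one
    platform beyond the others is assessed by comparing the joint walk with
    an analytically computed conditional walk in which that platform's
    ranking is randomised (a nested pair of hypergeometric expectations).
    One-sided Mann-Whitney comparisons of the walks classify each platform
    as dominant, subsumed or redundant for every gene set. Includes a
    kernel-density mutual-information gene scorer for categorical sample
    labels, a permutation false-discovery-rate calibration for the
    comparison threshold, and a simulator of planted combinatorial
    feature-membership relations used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
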