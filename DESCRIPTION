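Package: bacmeth
Title: Bacterial DNA Methylation Analysis from Nanopore Signal Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bacterial DNA methylation (6mA/5mC) from
    nanopore current-signal comparisons between native and whole-genome-amplified
    (WGA) DNA. Implements per-position two-sample signal testing (Mann-Whitney U
    and Welch t), coverage standardization by windowed read subsampling,
    empirical-null binary classification of methyltransferase motif sites (e.g.
    Dam GATC, Dcm CCWGG), in-silico methylation titration, genome-window
    methylation-fraction profiles with Pearson and coverage-adjusted partial
    correlations across growth conditions, and a long-range correlation scan.
    A synthetic-data module simulates genomes, per-molecule methylation
    landscapes, reads and signal event tables with the statistical structure the
    analysis assumes, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
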