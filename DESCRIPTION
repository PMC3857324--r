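Package: dcenet
Title: Differential Co-Expression Neighborhoods from Per-Individual Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differentially co-expressed genes from grouped,
    time-resolved expression data measured per individual. Builds a signed,
    significance-weighted co-expression network within each individual's own
    time series, retains gene pairs whose correlation is consistent across
    individuals in at least one group, and scores each gene by the proportion
    of its retained neighborhood whose group-averaged co-expression changes
    between groups (the DCeN score). Includes permutation significance,
    focal-gene switching neighborhoods, group-average / concatenation /
    individual-correlation baseline rankings, subsample reproducibility and
    gene-label permutation enrichment harnesses, and a synthetic cohort
    generator with individual-specific time warping and planted decoupled
    genes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr,
    knitr
Config/testthat/edition: 3
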