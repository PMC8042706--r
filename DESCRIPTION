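Package: ohnoshift
Title: Phylogenetic Ornstein-Uhlenbeck Tests for Expression Evolution After
    Whole Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adaptive shifts in gene expression level following a
    whole genome duplication using a multi-individual phylogenetic
    Ornstein-Uhlenbeck model. For each orthogroup the two-optima model (one
    expression optimum for a marked duplicate clade, one for the background)
    is compared against a single-optimum null by likelihood ratio, per-copy
    calls are combined into ohnolog pair categories, and downstream
    statistics (expression asymmetry, tissue concordance, promoter
    transposable-element load, bound transcription-factor-binding-site
    counts, enrichment and permutation tests) quantify the mode of
    regulatory divergence. Includes two-stage trimmed-mean-of-M-values
    normalization across species anchored on singleton orthogroups, gene
    tree topology filters, and a synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
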