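Package: barcodebin
Title: Concordance Between Species Taxonomy and Barcode Sequence Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for confronting traditional species-level taxonomy with
    operational taxonomic units delimited from COI DNA barcodes. Implements
    Kimura 2-parameter distances with pairwise deletion, BIN-style refined
    single-linkage clustering (single-linkage seeding followed by Markov
    clustering), neighbour-joining trees, barcode-gap statistics,
    species-to-cluster concordance classification (match, share, split,
    mixture), regional re-identification success, great-circle sympatry
    analysis, and a seeded synthetic barcode generator with planted ground
    truth for end-to-end validation.
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
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
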