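Package: fusenet
Title: Composite (Fused) Gene Detection in Sequence Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects composite (fused) genes as non-transitive triplet motifs
    in protein sequence similarity networks built from all-vs-all homology
    searches. Provides readers for BLAST tabular output and emapper-style
    functional annotations, network construction with per-edge alignment
    footprints, gene family assignment, a four-way remodelling
    classification (nested composite, strict composite, strict component,
    non-remodelled), equal-size class resampling, odds-ratio enrichment of
    composite genes in eukaryotes versus prokaryotes with Bonferroni-style
    corrected Woolf confidence intervals, and a synthetic-data generator
    with known fusion ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    igraph,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
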