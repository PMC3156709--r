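Package: bronx
Title: Alignment-Free DNA Barcode Identification with Nucleotide Exposes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An alignment-free sequence identification engine for DNA
    barcoding. Reference sequences are reduced to per-taxon composite
    "exposes": collections of short variable segments (text) together with
    their invariant flanking context (pretext and postext). Queries are
    scored by shared context at each taxonomic level, so that within-taxon
    variation and shared haplotypes yield honest ambiguity rather than
    false precision. The package also provides a classical pairwise
    matching baseline (Needleman-Wunsch and Smith-Waterman alignment with
    uncorrected p-distances and the barcode-gap criterion), an evaluation
    framework with weak/strong test classification, mini-barcode
    simulation, Wilson score intervals, Tukey-type comparisons of
    arcsine-transformed proportions and Fleiss' kappa, and a seeded
    simulator for two-marker plastid barcode datasets.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
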