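Package: snepr
Title: Single-Nucleosome Epi-Polymorphism Detection from Two-Strain Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls nucleosomes from tiling-microarray hybridization signal with a
    duration-structured sliding-window hidden Markov model, aligns the nucleosome
    maps of two yeast strains through whole-genome alignment blocks, and detects
    single-nucleosome epi-polymorphisms (SNEPs) -- nucleosomes whose histone-mark
    level (e.g. H3K14 acetylation) differs between strains -- with a per-nucleosome
    ANOVA interaction test under Benjamini-Hochberg FDR control. Includes
    gene-anchored profile and enrichment statistics, and a truth-annotated
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
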