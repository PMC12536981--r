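Package: pedpaint
Title: Parent-of-Origin Ancestry Painting for Experimental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic assignment of parent-of-origin ancestry to
    homozygous SNPs in offspring of known crosses. Labeled SNPs are
    collapsed into ancestry blocks by a two-pass run-length clustering
    algorithm (minimum tract length, then removal of small intervening
    blocks), parental contributions are quantified per chromosome at the
    nucleotide and gene level, and chromosomes are painted as composite
    segment plots. Includes a synthetic-cross simulator with known
    crossover truth sets so the whole pipeline can be validated end to
    end, and a command-line interface wrapping the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
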