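Package: splitmap
Title: Seed-and-Extend Split-Read Alignment for Structural Variant
    Breakpoint Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A hash-based seed-and-extend DNA aligner for long reads and
    assembled contigs, designed for split-read detection of structural
    variant breakpoints. Builds a 2-bit-packed k-mer index with a Reference
    Offset Array, collates seed matches with a query-length-way heap merge,
    merges same-diagonal seeds into exact-match fragments, chains fragments
    through a max-path directed acyclic graph under affine-gap scoring,
    completes alignments with banded affine-gap dynamic programming and
    X-dropoff extensions, and selects the Optimal Coverage Set of
    alignments along each query with a breakpoint penalty scaled by genomic
    distance, plus similarity-filtered secondary alignments. Includes a
    structural-variant and chromothripsis contig simulator, a read sampler
    with configurable error profiles, and a breakpoint verification metric,
    so the whole pipeline can be exercised end-to-end on synthetic genomes.
    Alignments are written as SAM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
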