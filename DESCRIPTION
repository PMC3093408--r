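Package: ervscape
Title: Endogenous Retrovirus Genome-Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome-wide analysis of endogenous retroviruses
    (ERVs) detected as proviral chains: locus filtering and deduplication,
    LTR-divergence molecular dating, sense/antisense gene-neighborhood
    profiling around integrations, chromosomal distribution and correlation
    statistics, assembly-gap candidacy classification, and Pol-putein
    comparative analysis (identity matrices, Kimura-corrected distances,
    neighbor-joining trees with bootstrap, dot-matrix screening).  Includes a
    deterministic synthetic-annotation generator that produces every input
    the pipeline consumes together with ground-truth sidecars for
    planted-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
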