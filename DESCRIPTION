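Package: drrekit
Title: Discovery and Classification of Damage-Responsive Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify the genes and regulatory elements that respond
    to tissue damage from expression and chromatin-accessibility data.
    Implements fold-change differential-expression calling on FPKM tables,
    sliding-window hypergeometric detection of chromosomal clusters of
    differentially expressed genes, replicate-concordant peak handling and
    differential accessibility, the emerging/increasing taxonomy of
    damage-responsive regulatory elements (DRREs) with reused/novel usage
    classification against reference open-chromatin collections, TSS-relative
    genomic annotation with precedence, active-enhancer feature marking from
    ChIP data, delta-delta-Ct qPCR fold enrichment, summit-anchored
    conservation profiling, and cross-species intersection of up-regulated
    ortholog sets. A seeded synthetic-study generator with planted ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
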