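Package: purplemap
Title: Two-Bulk Euclidean-Distance Mapping and Multi-Omics Integration
    for a Dominant Leaf-Colour Locus
Version: 0.1.0
Authors@R:
    person("Purplemap", "Developers", email = "purplemap@example.org",
           role = c("aut", "cre"))
Description: Bulked-segregant association mapping for F1 pseudo-testcross
    populations using the per-variant Euclidean-distance (ED) statistic on
    two-pool allele depths, applied to both genomic (BSA-seq) and
    transcriptomic (BSR-seq) variant layers.  Includes pooled RNA-seq
    differential-expression calling, three-way gene-set integration with a
    focal-gene correlation network, hypergeometric over-representation
    testing, assay-level mathematics (spectrophotometric anthocyanin
    quantification, 2^-ddCt relative expression, antisense-oligo selection
    filters, in-silico PCR for InDel functional markers, co-segregation
    testing, cis-element scanning), and a seeded synthetic F1-cross data
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
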