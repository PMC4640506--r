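Package: mirstarve
Title: Small RNA-Seq Quantification and No-Replicate Differential
    Expression of Starvation-Responsive microRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale small RNA-seq analysis workflow for identifying
    starvation-responsive microRNAs in Caenorhabditis elegans L4 larvae.
    Covers FASTQ cleanup (5' artificial-hexamer and 3' adapter trimming,
    16-28 nt length selection, collapsing to unique reads), end-to-end
    multi-mapping against a class-labelled reference (extended mature
    miRNAs, hairpins, non-coding transcripts, coding transcripts, genome),
    hierarchical class assignment with fractional multi-mapper counting,
    TMM-normalised two-library differential expression via a
    negative-binomial conditional exact test at fixed common dispersion
    with Benjamini-Hochberg FDR, Pfaffl efficiency-corrected qRT-PCR
    relative quantification, and a seeded synthetic-data generator with
    per-read ground truth so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
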