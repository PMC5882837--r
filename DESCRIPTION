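Package: mirnome
Title: miRNA Expression Variability and Differential-Response Analysis for
    Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for microRNA (miRNA) expression analysis from
    multiplexed small-RNA sequencing libraries: barcode demultiplexing,
    3'-adapter trimming, length filtering, read collapsing and exact-match
    quantification against a mature-miRNA reference; median-of-ratios
    (DESeq-procedure) count normalization; screening of replicate groups
    for hypervariable miRNAs (MAX/MIN ratio against a mean + 2 SD
    threshold) and for co-varying miRNA gene clusters; two-group
    differential expression by an exact Mann-Whitney test or a
    negative-binomial exact test with Benjamini-Hochberg false-discovery
    control; and validation of fold-changes through -5p/-3p partner-strand
    concordance and cross-comparison agreement. A seeded negative-binomial
    synthetic-data generator emulates the replicate structure, hairpin
    partner strands, co-varying clusters and planted fold-changes that the
    analysis assumes, so the whole chain is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
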