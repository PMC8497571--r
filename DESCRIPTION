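Package: bipair
Title: Bidirectional Gene Pairs, Pol II Pausing and Nascent-RNA Metagene Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strand-aware downstream analysis of nascent (4sU-seq), total
    RNA-seq and Pol II ChIP-seq experiments centred on bidirectionally
    transcribed gene pairs. Annotates each gene's nearest neighbours by
    direction and orientation, calls bidirectional promoters from
    opposite-strand TSS signal (CAGE peaks or stranded coverage), computes
    Pol II travelling ratios and scaled/reference-point metagene matrices
    with an unchanged-gene library normalization, derives intron/exon
    coverage ratios with median-of-ratios size factors, and tests gene-set
    enrichment with Fisher's exact test and resampling null bands. A
    synthetic-data generator with a full ground-truth table makes every
    stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    DESeq2,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
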