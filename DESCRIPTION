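Package: acrstage
Title: Stage-Resolved Chromatin Accessibility and Transcriptome Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of developmental-stage ATAC-seq and RNA-seq
    experiments, starting from replicate peak calls and read-count matrices.
    Builds stage consensus accessible chromatin regions (ACRs) by replicate
    intersection, annotates peaks to genomic feature classes around gene
    models, estimates fold enrichment against length-matched random regions
    by permutation, tests differential peak intensity and differential gene
    expression with a negative-binomial Wald test, integrates promoter ACR
    number and length with expression level, clusters temporal expression
    profiles, scores gene-set overlaps with the hypergeometric test, and
    scans peak-centered windows for position-weight-matrix motif enrichment.
    Includes a seeded synthetic-study generator with a machine-readable
    truth record so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
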