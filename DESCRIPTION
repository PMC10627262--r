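Package: promstab
Title: Core Promoter Architecture and Expression Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links gene expression uniformity, measured as the percentile
    rank of the coefficient of variation (CV) across tissue-atlas RNA-seq
    samples, to core promoter architecture (TATA-box, Y patch, Inr, CA, GA
    octamer classes, and Coreless promoters), and traces expression-pattern
    switches across orthologous gene groups on a species phylogeny. Count
    matrices are normalized with the median-of-ratios size-factor estimator;
    promoters are extracted from GFF3/FASTA annotation in a TSS-anchored
    coordinate system and labeled by position-weight-matrix scanning with a
    relative-score threshold and by positional octamer presence. A synthetic
    data module generates genomes with planted core promoter elements,
    negative-binomial tissue atlases with designed uniform and conditional
    genes, and multi-species ortholog families with planted expression
    switches, so every stage of the pipeline can be exercised and validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    DESeq2
Config/testthat/edition: 3
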