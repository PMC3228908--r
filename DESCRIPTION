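Package: aeiscope
Title: Allelic Expression Imbalance from Indexed Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies allelic expression imbalance (AEI) of candidate
    genes from PCR/next-generation sequencing assays in which pooled
    amplicons carrying a transcribed marker SNP are tagged with 5-bp
    sample indices and sequenced as single-end reads. Provides read
    demultiplexing and reference matching, marker-SNP allele counting
    with quality-control triage, AEI ratio computation with genomic-DNA
    based correction for allele-specific PCR amplification bias,
    empirical and binomial models of measurement error as a function of
    read depth, and a population-genetic model that predicts and fits
    ordered distributions of log2 AEI ratios across heterozygous samples
    in terms of cis-regulatory variants, their effect sizes and linkage
    disequilibrium to the marker SNP. A synthetic-data generator emulates
    the full study design for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Transcriptomics, GeneExpression, SNP, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
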