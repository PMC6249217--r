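Package: devomics
Title: Time-Resolved Multi-Omic Analysis of Organ Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for time-resolved proteome and transcriptome
    analysis of developing organs. Builds splice-junction peptide databases
    from assembled transcripts (novel-junction classification, in-silico
    splicing, 3-frame translation, fully tryptic digestion, reference-proteome
    novelty filtering), performs iBAQ-based iFOT label-free quantification
    with tiered identification filters, partitions developmental timepoints
    into phases by hierarchical clustering and PCA, identifies differentially
    expressed genes across phases by one-way ANOVA with Benjamini-Hochberg
    adjustment, groups coexpressed genes by Ward clustering, correlates
    protein and mRNA profiles on z-scores, and tests development-vs-cancer
    gene-set overlaps with a two-tailed hypergeometric test. A synthetic-data
    module generates every input with known ground truth so the full pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    fgsea,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
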