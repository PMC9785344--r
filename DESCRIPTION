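Package: noduleTx
Title: Nodule Transcriptome Analysis of Biological Nitrogen Fixation Efficiency
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for root-nodule transcriptome analysis of
    biological nitrogen fixation (BNF) efficiency in legumes. Implements
    median-of-ratios count normalization, replicate quality control,
    a negative-binomial Wald test for differential expression between
    high- and low-fixation genotypes, scanning of nodule-specific
    cysteine-rich (NCR) peptide candidates from protein sequences,
    gene-duplication-mode enrichment with a resampled expression-divergence
    null, signed-hybrid weighted co-expression module detection with module
    eigengenes and module-trait correlation, hypergeometric term enrichment
    with Benjamini-Hochberg FDR, and a seeded synthetic-data generator that
    plants ground truth for every downstream stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
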