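Package: scorescan
Title: Polygenic-Score-Level Association Scans from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests associations between a GWAS trait and many genetically
    imputed complex traits using only SNP-level summary statistics and an
    external linkage-disequilibrium reference panel. Implements univariate and
    multivariate (conditional) polygenic-score association z-scores, polygenic
    risk score construction by p-value thresholding and greedy LD clumping,
    genomic region exclusion, inverse-variance-weighted meta-analysis,
    clustering-based representative trait selection, hypergeometric replication
    enrichment, and a seeded simulation engine with an individual-level
    ordinary-least-squares oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
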