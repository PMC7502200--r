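Package: devnoise
Title: Inter-Individual Expression Variability Across Embryogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify inter-individual gene expression variability
    across developmental stages from replicate (single-embryo) RNA-seq count
    matrices. Implements mean-independent variability metrics (adjusted
    standard deviation, distance-to-median, coefficient of variation) on top
    of a quantile-normalization and batch-correction preprocessing pipeline,
    stage-specific gene detection by template-profile correlation,
    expression-weighted transcriptome indices of promoter sequence
    conservation with bootstrap confidence intervals, and intergenic-
    normalized promoter histone-signal analyses including Spearman partial
    correlations. A seeded synthetic-data generator produces count matrices,
    sample metadata and genome tracks with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    limma,
    edgeR,
    sva,
    Matrix,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
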