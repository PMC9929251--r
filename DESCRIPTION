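Package: scpoolr
Title: Iterated Pseudocell Pooling and Variance Partitioning for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Collapses sparse single-cell RNA-seq counts into randomly
    pooled fixed-size pseudocells within each sample and cell type,
    normalizes them to counts per 100,000, and partitions per-gene
    expression variance across crossed experimental random effects
    (stimulus, disease status, batch, donor, and the stimulus-by-status
    interaction) by REML with a method-of-moments fallback.  Also
    provides area-under-the-concordance-curve (AUCC) comparison of
    ranked gene lists, mixed-model ANOVA of per-sample cell-type
    proportions, cell-level quality-control filters, and a synthetic
    data generator with known ground truth for validating the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
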