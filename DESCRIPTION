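Package: greenswitch
Title: Temporal Chromatin Dynamics of the Methylation-to-Acetylation
    Switch at Photosynthesis Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing temporal histone-modification ChIP-seq
    experiments during the greening (de-etiolation) of plant cells.
    Implements consensus peak curation with a dual-control conservation
    rule and summit extension, H3-normalized moderated differential
    enrichment between consecutive timepoints, chromatin-trajectory
    classification including the late-acetylation Profile5 class and the
    H3K27me3-to-H3K27ac switch gene set, hypergeometric term
    over-representation with percent-found versus percent-expected
    ratios, ChIP-qPCR percent-input double normalization and delta-Ct
    expression, spectrophotometric chlorophyll and carotenoid
    quantification, green-pixel seedling phenotyping, and seeded
    synthetic-data generators with planted truth labels for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    multcomp,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
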