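Package: episignr
Title: DNA Methylation Episignature Discovery and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating peripheral-blood DNA
    methylation episignatures for rare genetic disorders from Infinium
    EPIC-style beta-value matrices. Implements moderated t-statistic
    differential methylation with empirical-Bayes variance shrinkage,
    episignature probe selection with iterative removal of
    signature-negative cases, a linear support-vector-machine classifier
    with Platt-calibrated methylation variant pathogenicity (MVP) scores
    and clinical call cutoffs, leave-25%-out cross-validation,
    hierarchical clustering and multidimensional scaling views, and
    cross-cohort comparative epigenomics (directional DMP overlap,
    tree-and-leaf aggregation, CpG-island shore/shelf annotation and
    enrichment). A seeded synthetic cohort generator with planted
    episignatures, mosaic attenuation and machine-readable ground truth
    supports end-to-end testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    withr,
    e1071,
    jsonlite,
    yaml,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
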