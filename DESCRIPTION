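Package: chromEGA
Title: Integrative Chromatin Accessibility and Expression Analysis of
    Pre-Implantation Embryo Stages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for staged chromatin-accessibility (CA)
    and gene-expression (GE) profiles across an ordered pre-implantation
    series (oocyte, sperm, zygote, cleavage stages, morula, ICM, TE).
    Provides replicate-consensus and unified peak processing on genomic
    intervals, median-of-ratios count normalization, promoter CpG-density
    classing (HCP/ICP/LCP), time-course fuzzy c-means clustering with
    membership thresholding, embryonic genome activation (EGA) gene calling
    with promoter/distal peak decomposition, ChIP binding-site overlap
    statistics against stage-gained accessible regions, Shannon-entropy
    stage-specificity scoring for retrotransposon families, and 2-Mb
    genome-window gene-density correlation. A fully deterministic
    synthetic-data generator emulates the multi-stage design with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    DESeq2,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
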