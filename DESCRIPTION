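Package: chipmetrics
Title: Quantitative ChIP-seq Occupancy, Metagene Profiles, and Pol II
    Pausing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative comparison of ChIP-seq signal between
    conditions: per-sample size factors estimated from large intergenic
    background regions (median-of-ratios) or from total mapped reads,
    per-gene occupancy densities for gene-body chromatin marks such as
    H2Bub1, fixed-bin metagene and TSS-centered average profiles with
    k-means signal clustering, the RNA polymerase II traveling ratio
    (pausing index) with two-sample Kolmogorov-Smirnov comparison of its
    cohort distribution, bookkeeping for differential-expression tables
    (thresholding, fold-change bins, overlaps, cross-study correlation),
    and a seeded generator of synthetic genomes and tag libraries with
    planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
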