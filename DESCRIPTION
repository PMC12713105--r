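Package: dsbloop
Title: DNA Double-Strand Breaks and 3D Genome Reorganization Under Folate Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis linking folate-deficiency-induced DNA
    double-strand breaks (DSBs) to chromatin three-dimensional reorganization.
    Provides per-bin DSB ratio quantification with hypergeometric enrichment
    tests, probability-threshold differential chromatin-loop calling from
    probability-scored loop lists, aggregate peak analysis (APA) on sparse
    contact matrices, busy-anchor (interaction hub) association statistics,
    chromatin-state stratified correlation analyses (TSS distance, ratio
    deciles, enhancer proximity, peaks, repeats), compartment and hierarchical
    TAD association, expression coupling, and multi-evidence gene
    prioritization. A fully deterministic synthetic-data generator with
    planted ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
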