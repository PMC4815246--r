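Package: dipseqr
Title: DIP-Seq Enrichment Segmentation and Differential Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for MeDIP-Seq and hMeDIP-Seq (DIP-Seq) tag
    libraries: Monte-Carlo sliding-window segmentation of enriched 5mC/5hmC
    domains with an empirical false-discovery threshold, chi-square and
    negative-binomial differential region calling between conditions with
    Benjamini-Hochberg adjustment, directional spatial-overlap statistics
    between differentially methylated and hydroxymethylated regions,
    genomic-category and repeat-class density summaries, expression-ranked
    metagene density matrices, and fixedStep wiggle export. Includes a
    synthetic-data generator that plants enriched domains and differential
    regions with known truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
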