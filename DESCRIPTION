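Package: agesplice
Title: Cohort Transcriptome Aging Analysis with Percent-Spliced-In
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing bulk RNA-seq transcriptomes between two
    age cohorts: junction-read percent-spliced-in (PSI) quantification of
    cassette exons from splice-aware alignments, cohort delta-PSI
    comparison, counts-per-million detection and cohort-exclusive gene
    logic, fold-change categorization of differential-expression tables,
    leading log-fold-change multidimensional scaling, gene-set
    overrepresentation with fold enrichment and false-discovery-rate
    control, and delta-delta-Ct qPCR cross-validation.  Includes a
    splice-aware synthetic data generator with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
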