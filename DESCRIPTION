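Package: placentamir
Title: Small RNA Quantification and Placental miRNA Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for small RNA sequencing analysis of
    trophoblast differentiation and placental miRNA biomarkers. Implements
    barcode demultiplexing with Hamming-distance codes, mismatch-tolerant
    3' adapter trimming, dinucleotide-entropy low-complexity filtering,
    mature-miRNA quantification with reads-per-million normalization and a
    pseudocount log2 transform, qPCR delta-Ct cohort statistics with
    Mann-Whitney comparisons and a miR210/miR455 ratio biomarker with ROC
    analysis, and dual-luciferase repression analysis. A seeded synthetic-data
    generator emulates multiplexed small RNA libraries, differentiation
    experiments, placenta cohorts and luciferase plates for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
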