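Package: celtilr
Title: CelTIL Scoring and Early-Response Biomarker Analysis for Window-of-Opportunity Breast Cancer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translational analysis of paired-biopsy
    window-of-opportunity breast cancer studies. Computes the combined
    cellularity/tumor-infiltrating-lymphocyte (CelTIL) score and
    treatment-response calls from baseline and day-21 biopsies, normalizes
    targeted expression-panel counts against housekeeping genes, calls
    intrinsic molecular subtypes by nearest centroid, scores RNA and
    copy-number signatures (including a 17q12/ERBB2 amplicon signal),
    applies somatic-variant read-support and population-frequency filters,
    and runs the association statistics used for biomarker discovery:
    significance analysis of microarrays (SAM) with permutation-based FDR,
    exact contingency tests, logistic odds ratios, and rank-based ROC AUC.
    A seeded synthetic-cohort generator produces trial-shaped clinical,
    expression, copy-number and mutation data with planted effects so the
    whole pipeline is testable without access to restricted patient data.
License: MIT + file LICENSE
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
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
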