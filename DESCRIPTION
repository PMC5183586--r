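Package: fcgr3cnv
Title: Multi-Assay Copy-Number Calling and Concordance Analysis for the
    FCGR3 Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines integer genomic copy numbers of the paralogous
    low-affinity Fc gamma receptor genes FCGR3A and FCGR3B from four
    laboratory assay signal types: TaqMan duplex quantitative PCR, SYBR
    Green quantitative PCR with the relative standard-curve method, the
    paralog ratio test combined with restriction enzyme digest variant
    ratios resolved by maximum likelihood, and a microsatellite (MSAT1)
    dosage assay with polymerase-slippage (stutter) correction.  Provides
    a consensus integrator that combines calls from several methods, an
    evaluation layer computing pairwise and multiway concordance rates,
    Pearson correlation against continuous array-style dosage, and
    per-copy-number error-direction profiles, plus a synthetic cohort
    generator that emulates the assay signal models so the whole pipeline
    is testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
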