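Package: immunoreact
Title: Immune-Focused Transcriptome Survival Analysis for Ovarian Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for immune-focused analysis of bulk
    tumour transcriptomes across multi-study ovarian cancer cohorts:
    probe-to-gene collapse and per-study standardisation of expression
    tables, a univariate proportional-hazards screen over immune gene
    panels with expected-false-positive accounting, discovery of an
    immunoreactive prognosis subgroup by hierarchical clustering with
    centroid-seeded label transfer to validation cohorts, volcano-style
    differential marker tests, shrinkage partial-correlation graphs over
    immune metagenes with a latent-mediator (hidden node) search, and a
    BIC-stepwise logistic model predicting immunoreactive status from
    cancer-testis antigen expression. A synthetic multi-study cohort
    generator with planted ground truth supports calibration and
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
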