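Package: romma
Title: Rochester Modified Magee Algorithm for Oncotype DX Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and triage engine for estrogen-receptor-positive breast
    cancer cases built around the Rochester Modified Magee algorithm (RoMMa).
    Computes modified Magee recurrence scores from routine clinicopathologic
    variables (Nottingham score, ER/PR H-scores, HER-2 status, Ki-67, tumor
    size), applies threshold and histologic low-risk rules to recommend which
    cases need send-out Oncotype DX testing, and provides the companion
    validation analytics: band-agreement tables against the Oncotype DX
    recurrence score, 2x2 diagnostic-accuracy metrics with Fisher exact tests,
    recurrence-outcome associations, and institutional/national cost-avoidance
    modeling. Includes a seeded synthetic-cohort generator so every stage is
    testable without patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
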