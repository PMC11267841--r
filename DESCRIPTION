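Package: icufidelity
Title: Exposure Scoring and Process-Evaluation Metrics for an ICU
    Fluid-Balance Strategy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a per-patient score of actual exposure to a
    daily-weighing fluid-balance control strategy in intensive care:
    protocol deviations are counted on fluid-overloaded, non-contraindicated
    days inside a Day 2-14 window and the resulting deviation rate is
    weighted by weighing completeness, yielding a 0-100 fidelity index.
    Also provides the descriptive reach, dose/fidelity and
    mechanisms-of-change summaries used in stepped-wedge trial process
    evaluations, an unweighted Cohen's kappa for intercoder agreement, a
    seeded synthetic patient-day cohort generator for end-to-end testing
    without trial data, and a reproducible simulate-score-summarize
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
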