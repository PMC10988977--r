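Package: apbicea
Title: Markov Cohort Cost-Effectiveness Analysis of Accelerated Partial
    Breast Irradiation Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic four-state Markov cohort model comparing
    electron-based intraoperative radiotherapy (IORT) with
    intensity-modulated radiotherapy (IMRT) after breast-conserving
    surgery in early breast cancer, from a health-provider disinvestment
    perspective.  Provides time-dependent transition matrices built from
    annual recurrence and mortality probabilities, derivation of those
    probabilities from trial-style cumulative incidence and overall
    survival curves, discounted life-year / quality-adjusted outcome and
    cost accounting, incremental cost-effectiveness ratios with dominance
    classification, one-way sensitivity and scenario analyses, a
    convention-calibration harness, synthetic trial-curve generators for
    validation, and CSV/JSON reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
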