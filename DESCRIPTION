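Package: gdftroi
Title: Budget Impact and Return on Investment of Goal-Directed Fluid
    Therapy in Major Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the hospital cost burden of postsurgical
    complications and projecting the economic impact of perioperative
    goal-directed fluid therapy (GDFT). Provides a synthetic patient-level
    claims-cohort generator parameterized by published procedure-level
    morbidity, cost, length-of-stay and readmission estimates; group-level
    descriptive summaries and two-group comparisons (Welch t, Wilcoxon
    rank-sum, chi-squared); confounder-adjusted cost contrasts via a gamma
    generalized linear model with log link and least-squares means; and the
    budget-impact core: odds-ratio-based morbidity projection, gross and
    per-patient cost-savings, return-on-investment against monitoring
    implementation costs, and bed-day opportunity-cost capacity gains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
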