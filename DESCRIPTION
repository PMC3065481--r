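Package: refillcea
Title: Cost-Effectiveness Analysis of Pharmacy-Only ART Refill Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the cost-effectiveness of a pharmacy-only
    antiretroviral therapy (ART) refill program against standard
    physician-led care in a high-volume HIV clinic. Implements a two-strategy
    decision model with per-category annual costs under limited-societal and
    Ministry-of-Health perspectives, incremental cost-effectiveness ratios
    with cost-effectiveness-plane quadrant semantics, net monetary benefit,
    one-way (tornado) sensitivity analysis, and probabilistic sensitivity
    analysis with moment-matched beta and gamma parameter distributions,
    cost-effectiveness plane scatter summaries and acceptability curves.
    Also provides a synthetic retrospective-cohort generator with confounded
    arm assignment and a logistic favourable-immune-response outcome, plus
    odds-ratio estimation (crude and covariate-adjusted) for the
    effectiveness stage.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
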