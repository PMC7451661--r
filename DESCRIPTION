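Package: aboin
Title: Adaptive Bayesian Optimal Interval Designs for Phase I Dose-Finding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating phase I dose-finding trials
    with Bayesian optimal interval (BOIN) rules and two extensions: decision
    boundaries that incorporate historical information through prior
    probabilities of three point hypotheses, and adaptive boundaries that
    shrink toward the target toxicity rate as patients accrue at a dose.
    Includes an automatic prior-elicitation algorithm that expands an
    investigator's per-dose MTD confidence vector into a full hypothesis
    probability table, a cohort-by-cohort trial-conduct engine with
    posterior-probability safety elimination and isotonic-regression MTD
    selection, and a Monte-Carlo simulator of operating characteristics
    (correct-selection rate, patient allocation, overdosing and underdosing
    risk) over configurable dose-toxicity scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
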