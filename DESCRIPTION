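Package: goalpursuit
Title: Normative Modelling of Prioritization During Multiple-Goal Pursuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying how decision makers prioritize two competing
    approach or avoidance goals in a multistage task. Formalizes a two-goal
    pursuit trial as a finite-horizon Markov decision process, solves it
    exactly by backward induction, and computes goal-attainment
    probabilities under the optimal policy. Includes calibration of a
    factorial experimental design to target dual-goal difficulty levels, a
    synthetic-data generator with optimal and risk-biased agents, and an
    analysis pipeline that codes decisions against the normative model,
    applies exclusion rules, and estimates the goal frame by decision
    source interaction with cluster-robust logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
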