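Package: effortbf
Title: Order-Constrained Bayes Factor Analysis of Effort-Based Task Choices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling effort-based decision-making among cognitive
    task options that differ in demand level and task type. Builds per-participant
    preference rankings (demand-avoidant and challenge-seeking models derived
    from practice accuracy, plus fixed task-order models), compares them on
    pairwise forced-choice data with encompassing-prior Bayes factors, classifies
    participants as demand-related, task-driven or no-best-fit, and tests for
    single-task biases. Also implements an adjusting-offer titration procedure
    for reward (francs) and demand (squares) incentive phases with final-offer
    scoring, between-subject z-score/kurtosis/correlation summaries, and a
    synthetic-agent cohort simulator with known ground-truth policies for
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
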