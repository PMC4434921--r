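Package: affectrl
Title: Dynamic Reward Task Simulation, Hierarchical Bayesian Q-Learning, and
    Feedback ERP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for model-based analysis of probabilistic reward learning
    under affective priming: a simulator for a dynamic two-deck reward task
    with un-signaled block reversals, a Q-learning/softmax choice model fit
    by hierarchical Bayesian Markov chain Monte Carlo with convergence and
    group-comparison diagnostics, a feedback- and prime-locked EEG/ERP
    pipeline producing General, Expected and Unexpected feedback-related
    negativity (FRN) difference waves, behavioral summaries (rich-deck choice
    curves, learning-state splits, non-reward run statistics), and a
    synthetic-data generator so that every stage is testable by parameter and
    amplitude recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
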