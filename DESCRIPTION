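Package: heistrl
Title: Context-Dependent Sharing of State-Transition Models in a Two-Stage Planning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the two-stage "heist" planning task, in which two visual
    contexts per block share a single state-transition probability (dependent
    condition) or follow unrelated schedules (independent condition), and
    implements the dual-learner reinforcement-learning model used to analyse
    behaviour on it: a context-independent and a context-specific transition
    learner mixed by a weight that may reverse between conditions. Provides
    hierarchical Expectation-Maximization fitting with Gaussian group priors
    and Laplace-approximate evidence, subject-level leave-one-out
    cross-validation and model comparison, trial-history evidence regressions
    with an agent-based permutation null, outcome-valence consistency scores,
    a synthetic multivoxel pattern generator with shared or context-specific
    codes, representational similarity analysis with Fisher-z on/off-diagonal
    contrasts, and a cross-validated probability encoding model scored by
    cross-entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
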