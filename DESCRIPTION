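Package: retreatCBR
Title: Case-Based Reasoning Decision Support for Dental Retreatment
    Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A case-based reasoning (CBR) pipeline for predicting failure
    of endodontic retreatment from categorical clinical variables. The
    reuse stage combines two discrete Bayesian-network classifiers --
    one learned by score-based tabu search under a K2-style
    Bayesian-Dirichlet score, one by conditional-independence search --
    through a false-negative-averse constrained least-squares mixture
    solved in closed form with Lagrange multipliers. The revise stage
    screens variables with a chi-square / Yates / Monte-Carlo /
    Fisher-exact battery, and the evaluation harness provides
    leave-one-out accuracy, ROC AUC, 5x2 cross-validation, Dietterich's
    paired t-test and Mann-Whitney U comparisons. A synthetic generator
    emulates the clinic-scale case table so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
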