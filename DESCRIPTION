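Package: iwcst
Title: Simulation and Bayesian Analysis of an Internet-Based Wisconsin
    Card-Sorting Task
Version: 0.1.0
Authors@R: person("iwcst", "maintainers", email = "iwcst@example.org",
    role = c("aut", "cre"))
Description: A task engine for an internet-based Wisconsin card-sorting
    task with constrained pseudo-random target sequencing, the full
    perseveration-error taxonomy (repetitive and non-repetitive
    perseverations, set-loss, integration and odd errors), parametric
    synthetic participants, and the Bayesian confirmatory layer used to
    test the error suppression effect: JZS Cauchy-prior paired-samples
    Bayes factors, effect-size posteriors, order-constrained hypothesis
    evaluation via the encompassing prior, and Pearson-correlation Bayes
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
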