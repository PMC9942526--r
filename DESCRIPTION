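Package: ptlearn
Title: Prospect-Theory Decision Models with Value Learning for Risk and
    Ambiguity Gambling Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and fitting pipeline for an eight-condition
    gambling task measuring risk, loss, and ambiguity aversion.
    Implements a space of 50 candidate models crossing five
    prospect-theory decision rules (differing in how multiplicative
    ambiguity weights are tied across risky/sure gain/loss contexts)
    with ten value-learning rules for ambiguous outcome magnitudes
    (no-learning baseline, Rescorla-Wagner with single or asymmetric
    learning rates, and a Bayesian mean tracker, each under three
    starting-value schemes). Provides a synthetic-cohort generator,
    per-subject MAP and empirical-Bayes hierarchical fitting with
    Laplace posterior draws, WAIC model comparison with stacking
    weights, Efron's pseudo-R2, calibration tables, model-agnostic
    behavioral aversion measures, subject-exclusion filters, group
    bias tests, and parameter/model recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
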