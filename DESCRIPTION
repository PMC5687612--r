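Package: pickwinner
Title: Bayesian Pick-the-Winner Design for Randomized Phase II Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and evaluation of two-arm randomized phase II
    "pick-the-winner" trials that run a Simon two-stage futility design in
    each arm and, when both arms pass the second stage, declare a winner by
    the Bayesian posterior probability that one arm's response rate exceeds
    the other's. Provides exhaustive search for optimal and minimax Simon
    two-stage designs, conjugate beta-binomial posterior inference with a
    family of reference priors, exact operating characteristics of the full
    two-arm procedure by outcome enumeration, seeded Monte Carlo trial
    simulation, one-sided Fisher exact test and single-stage randomized
    trial comparators, and a protocol-ready statistical plan generator with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
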