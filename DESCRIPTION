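Package: minmaxfit
Title: Fitness-Proportional Attachment from Minmax-Exposure Games
Version: 0.1.0
Authors@R:
    person("Avery", "Whitmore", email = "avery.whitmore@example.org",
           role = c("aut", "cre"))
Description: Solvers and simulators for a behavioural mechanism behind
    fitness-based preferential attachment in growing networks. Attachment
    probabilities that minimise the maximum expected exposure to node
    unfitness (the reciprocal of node fitness) are computed three ways: in
    closed form, by a linear program with dual extraction, and by iterative
    two-player zero-sum game algorithms based on the method of successive
    averages, for both homogeneous node sets and tiered (multipartite)
    systems such as supply chains, where the iterative scheme uses a layered
    shortest-path step instead of path enumeration. A network growth
    simulator grows graphs under degree, degree-times-fitness, and pure
    fitness attachment kernels with lognormal fitness, together with
    degree-distribution diagnostics, reproducible fixture generators, and a
    command-line interface over plain TSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
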