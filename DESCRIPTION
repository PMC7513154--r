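Package: evbic
Title: Hybrid Bayesian Network Structure Learning with Explicit and Vague
    Expert Knowledge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure learning for discrete Bayesian networks that combines
    constraint-based initialisation (maximal-information-coefficient skeleton
    plus conditional-independence pruning and v-structure orientation) with a
    binary particle swarm search over directed acyclic graphs.  Knowledge from
    multiple heterogeneous experts -- both explicit statements that fix the
    causal state of a node pair and vague statements that only restrict it --
    is fused by credibility-weighted roulette selection, applied to the
    initial structure through probabilistic edge rules, and incorporated into
    the search through the EVBIC score, a BIC penalised by the log-likelihood
    of the expert reports.  Includes forward sampling, simulated experts with
    six accuracy parameters, BIF and plain-text network input/output, the
    Asia and Alarm benchmark structures, structural Hamming distance
    evaluation, and an experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
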