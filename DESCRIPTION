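Package: consensusmove
Title: Collective Movement Decisions from High-Resolution Group Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract and analyse shared movement decisions in
    cohesive animal groups tracked with synchronous high-frequency GPS.
    Implements dyadic pull/anchor initiation-attempt extraction from
    inter-individual distance extrema, chain-rule aggregation of attempts
    into multi-initiator events, directional agreement from circular
    variance, influence matrices and randomized-Elo dominance hierarchies
    with permutation tests, cluster-robust binomial models of follower
    decisions, compromise-versus-choose regime classification via dip and
    converging-modes tests, von Mises mixture clustering of initiator
    directions, and majority-rule sigmoid fits. Includes an agent-based
    synthetic trajectory generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    sandwich,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
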