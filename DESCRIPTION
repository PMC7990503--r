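Package: moralcost
Title: Computational Modelling of Moral Costs in Bribe-Taking Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how a power-holder decides whether to accept a
    bribe. Provides the bribery-game task design (payoff construction for
    proposer, power-holder and third party across Solo/Dyad and
    Bribe/Control conditions), a family of seven social-utility choice
    models with moral-cost parameters, hierarchical Bayesian estimation via
    a built-in No-U-Turn sampler, PSIS-LOO model comparison, parameter
    recovery and posterior predictive checks, and multivariate
    neural-similarity analyses (inter-subject representational similarity,
    cross-condition pattern similarity, and leave-one-subject-out decoding)
    with permutation inference. A synthetic-data generator produces
    complete studies (choices and subject-by-voxel pattern matrices with
    plantable structure) so the full pipeline runs end-to-end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    e1071,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    pROC,
    withr
Config/testthat/edition: 3
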