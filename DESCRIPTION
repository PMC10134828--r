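Package: growthfx
Title: Predicting Directed Growth Effects in Bacterial Cocultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and predicting how bacterial species affect
    each other's growth across carbon environments. Computes directed growth
    effects as the log ratio of a species' coculture and monoculture yields,
    builds phylogenetic and metabolic-profile principal-component features,
    trains machine-learning and naive baseline models for effect sign and
    strength, runs leave-one-species and leave-one-environment ablations,
    and interprets fitted models via sampling Shapley attributions and the
    maximal information coefficient of reciprocal effects. Includes a
    synthetic coculture-screen generator emulating the statistical structure
    of droplet-based pairwise interaction screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    MASS,
    xgboost,
    ranger,
    class,
    caret,
    pROC,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
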