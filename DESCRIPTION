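Package: beeallometry
Title: Allometric Scaling of Bee Mouthparts and Trait Prediction from
    Body Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits interspecific log-log allometric models of bee mouthpart
    length (proboscis, glossa, prementum) on intertegular distance, a
    standard proxy for bee body size, across bee families.  A fixed
    candidate set of ordinary least-squares models (family or tongue-group
    intercepts, common or group-specific scaling exponents) is compared by
    AIC, and the best-supported model is parameterized as an allometric
    power function L = exp(a_f) * IT^b.  The fitted coefficients predict
    mouthpart lengths and, through published body-size regressions,
    typical and maximum foraging distances for museum-measured species.
    Includes phylogenetic comparative tests of trait-environment
    association (phylogenetic generalized least squares under Brownian
    motion, and linear mixed models with nested taxonomic random effects),
    tools to prune backbone phylogenies and graft congeneric species as
    equal-branch-length polytomies, and a synthetic-data generator for
    specimens, ultrametric trees and Brownian traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
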