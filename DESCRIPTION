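Package: domfit
Title: Dispersal-Observation Models for Stream Fish Mark-Recapture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a joint dispersal-observation model to one-dimensional
    capture-mark-recapture data from stream fishes. Movement between
    consecutive sampling occasions follows a heavy-tailed Student-t kernel
    whose dispersion is a log-linear function of intrinsic (body size) and
    extrinsic (distance-weighted fish density, habitat) covariates with a
    log time-interval offset; an observation layer accounts for imperfect
    recapture and permanent emigration beyond the study reach. Includes
    detection-corrected distance-weighted density covariates, an adaptive
    Metropolis-within-Gibbs sampler (marginalized or latent-location
    augmented), split-chain R-hat diagnostics, posterior summaries with
    predictive movement bands, and a synthetic-data generator for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
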