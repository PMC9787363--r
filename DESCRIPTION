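Package: songmark
Title: Integrated Mark-Recapture and Acoustic Estimation of Animal Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian estimation of population size for multi-guild animal
    communities by integrating continuous-time mark-recapture data with counts of
    acoustic detections. Capture histories are modelled as a homogeneous Poisson
    process (exponential time to first capture, Poisson recaptures), acoustic
    detections as binomial counts of listening periods with at least one
    vocalization, and the two observation processes are conditionally independent
    given a latent Poisson population size which is marginalized analytically.
    Includes a generative simulator, an adaptive Metropolis-within-Gibbs sampler
    with Gelman-Rubin diagnostics and highest-posterior-density intervals, a
    mark-recapture-only comparison model, and runners for simulation studies and
    survey-effort trade-off sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
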