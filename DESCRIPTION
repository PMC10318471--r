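Package: msmfi
Title: Marginal Structural Models for Time-Varying Food Insecurity and Memory Decline
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate the effect of a time-varying binary exposure
    (food insecurity) on the trajectory of a repeatedly measured continuous
    outcome (a standardized memory score) in longitudinal panel studies with
    exposure-confounder feedback, informative loss to follow-up, and death as
    a competing event. Implements stabilized inverse-probability-of-treatment
    and censoring weighting, weight cumulation and percentile truncation,
    positivity and covariate-balance diagnostics, inverse-probability-weighted
    growth models (mixed-effects and GLS-independence), person-level bootstrap
    confidence intervals, the excess-years-of-aging translation of slope
    differences, and the standard sensitivity analyses (exposure recoding,
    complete case, time-invariant health confounders, alternative childhood
    socioeconomic covariates). Includes a synthetic biennial-cohort generator
    with known causal truth for validating the estimation pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
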