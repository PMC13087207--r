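Package: senescurve
Title: Reproductive Senescence Trajectories and Life-History Strategies in
    Long-Lived Breeders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying reproductive senescence from longitudinal
    breeding records of individually marked animals. Fits a hierarchical
    Bayesian binomial age-trajectory model (quadratic age effects with
    per-individual random intercepts and slopes, population-specific
    covariance matrices, year and cohort random intercepts) via MCMC;
    derives per-individual life-history parameters from the fitted
    logit-quadratic curves (age at onset of senescence, senescence rate at
    the post-peak inflection point, early-life and peak breeding
    performance); compares populations through kernel-density overlap
    coefficients with bootstrap standard errors, among-individual variance
    ratios and onset-rate correlations; and relates lifetime reproductive
    success to senescence parameters with Poisson regression and
    posterior-resampling uncertainty propagation. Includes a synthetic
    breeding-history generator for two populations with contrasting
    environments and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
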