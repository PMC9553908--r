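Package: behavpart
Title: Variance Partitioning of Repeated Behavioral Trials Across Native
    and Invasive Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian variance partitioning for repeated behavioral
    measurements in hierarchically structured populations (individuals
    nested in populations nested in regions). Fits heterogeneous-variance
    hierarchical Gaussian models by blocked Gibbs sampling, in which
    among-individual and/or within-individual variances may differ between
    groups, compares candidate random-effect structures by WAIC and
    Pareto-smoothed importance-sampling leave-one-out cross-validation
    (PSIS-LOO), and derives adjusted repeatability, posterior variance
    contrasts, group-mean contrasts, and among-individual trait
    correlations (behavioral syndromes) from region-varying multivariate
    random intercepts. Includes a synthetic trial-data generator that
    emulates the nested sampling design of a multi-region skink invasion
    study, plus preprocessing (trial filtering, trait transformation,
    standardization) and an end-to-end pipeline with a thin command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
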