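Package: sipeb
Title: Structurally Informed Parametric Empirical Bayes for Effective Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of fMRI effective connectivity with
    structural (tractography-derived) priors. Subject-level dynamic causal models
    (bilinear neuronal dynamics coupled to balloon haemodynamics) are inverted by
    variational Laplace; subjects are pooled in a second-level Bayesian general
    linear model with parametric random effects (Parametric Empirical Bayes, PEB);
    and hundreds of alternative second-level priors, obtained by passing structural
    connection strength through a parameterised sigmoid, are scored analytically by
    Bayesian model reduction to find the structure-function mapping with maximal
    model evidence. Includes a synthetic-cohort generator, free-energy diagnostics,
    and an end-to-end pipeline writing plain-text artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
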