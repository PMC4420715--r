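Package: pacfcov
Title: Bayesian Covariance Modeling for Irregular Longitudinal Data via
    Partial Autocorrelations
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semiparametric Bayesian models for the covariance structure of
    irregularly observed continuous longitudinal data, parameterized through
    the partial autocorrelation function (PACF) on a discrete time grid.
    Banded stationary and non-stationary PACF regression models (the latter
    with low-rank thin-plate penalized splines) are combined with a
    log-linear marginal variance function and a random intercept, and with
    conditional linear models in the observed dropout time for the mean so
    that informative dropout can be accommodated.  Inference is by Markov
    chain Monte Carlo (conjugate Gaussian mean updates plus adaptive
    random-walk Metropolis covariance updates); model comparison uses the
    deviance information criterion on the marginal likelihood, marginal
    covariate effects are obtained by the Bayesian bootstrap over the
    empirical dropout distribution, and model adequacy is assessed with a
    chi-square posterior predictive check.  A synthetic-data generator with
    irregular gap times and dropout, a long-format CSV interface, and a
    command-line entry point are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
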