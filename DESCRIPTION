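Package: countcast
Title: Multivariate Count Time Series: Conditional-Intensity and State-Space Models with Probabilistic Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, estimation and probabilistic forecasting for multivariate
    time series of counts. Covers observation-driven conditional-intensity models
    (linear INGARCH/MACI and log-linear autoregressions, fitted by quasi-maximum
    likelihood with analytic derivative recursions and sandwich standard errors)
    and a parameter-driven nonlinear Poisson state-space model with a Gaussian
    VAR latent process, fitted by particle marginal Metropolis-Hastings on top
    of a bootstrap particle filter with forward-filtering backward-sampling
    smoothing. Includes multivariate Poisson constructions via shared shocks
    (trivariate reduction), six proper scoring rules for count forecasts, and a
    benchmark driver comparing the model families on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
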