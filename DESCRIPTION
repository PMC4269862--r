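Package: afspower
Title: Sample-Size Power of Allele Frequency Spectrum Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation machinery for studying how sample size and event
    timing govern the power of demographic inference from the allele
    frequency spectrum (AFS). Computes expected one- and two-population
    spectra under piecewise-exponential demographic models by a
    finite-difference solution of the neutral Wright-Fisher diffusion with
    Richardson grid extrapolation, generates Poisson replicate datasets,
    fits competing models by maximising the Poisson composite likelihood
    with a bounded quasi-Newton optimiser in log-parameter space, and
    quantifies model-selection power (AIC, Akaike weights) and parameter
    recovery (RMSE, Fisher-information confidence intervals, coverage).
    An independent structured-coalescent simulator provides Monte-Carlo
    cross-checks of the diffusion spectra via Anscombe Poisson residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
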