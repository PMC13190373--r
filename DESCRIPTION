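Package: movetarget
Title: Animal Movement Models Consistent with a Parametric Utilisation
    Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and simulates continuous-time animal movement models
    whose long-run (stationary) distribution of location is, by construction,
    a specified parametric utilisation distribution built from spatial
    covariates and selection coefficients. Includes targeted diffusions
    (Langevin, kinetic Langevin, position-dependent diffusion rate, and a
    polar speed-and-bearing formulation with Rayleigh stationary speed),
    velocity-jump processes generalising the bouncy particle sampler
    (half-space bounces with Rice-distributed parallel speeds, smooth
    reorientation kernels, autocorrelated refreshment) simulated exactly by
    uniformisation/thinning, multi-state behavioural switching with
    location-dependent generators that preserve the joint location-state
    distribution, joint models for interacting individuals that preserve each
    individual's marginal utilisation distribution, stationarity diagnostics,
    and Euler-Maruyama pseudo-likelihood estimation of selection and speed
    parameters from regularly observed tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
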