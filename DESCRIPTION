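Package: dynfcr
Title: Dynamic Functional Concurrent Regression for Sparse Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits functional concurrent regression models with time-varying
    coefficient functions and a spline-based functional random intercept for
    irregularly and sparsely observed longitudinal data. Error-contaminated
    time-varying covariates are denoised by sparse functional principal
    component analysis, coefficient functions are estimated by penalized
    generalized least squares with difference penalties, and future
    trajectories of new subjects are predicted dynamically via best linear
    unbiased prediction with pointwise prediction intervals. Includes the
    classical competitor models (additive model, additive mixed model with
    random intercept and slope, covariate-free functional random intercept
    model) and a reproducible simulation benchmark with integrated squared
    error and coverage metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
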