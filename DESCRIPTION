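Package: firiglm
Title: General Linear Model Analysis of Functional Infrared Imaging Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Model-based inference of autonomic sympathetic arousal from
    functional infrared imaging (fIRI) thermal time series. Implements a
    canonical thermal response function (a Gaussian-smoothed causal
    bi-exponential, evaluated in closed form), event-related stimulation
    schedules and design-matrix construction, zero-phase Butterworth
    preprocessing and artifact correction, per-window general linear model
    inference with autocorrelation-corrected effective degrees of freedom,
    linearity and time-invariance validation statistics (first principal
    component templates, repeated-measures ANOVA on response weights,
    variance-ratio tests), robust bi-square fitting of response-function
    parameters, head-to-head agreement analysis against a GLM applied to
    skin conductance, and a synthetic cohort simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
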