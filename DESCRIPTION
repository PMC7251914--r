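Package: admbma
Title: Model-Based Meta-Analysis of Alzheimer's Disease Progression from
    Aggregate Trial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a literature-aggregate disease progression model for the
    placebo arms of Alzheimer's disease trials: linear progression of the
    ADAS-cog mean change plus an Emax-type placebo effect, with bivariate
    study-level random effects, covariate functions (power, linear, and
    inverse U-type), and residuals weighted by the square root of the
    per-time-point sample size. Provides approximate marginal-likelihood
    estimation (Laplace, with an adaptive Gauss-Hermite oracle), stepwise
    likelihood-ratio covariate screening, nonparametric bootstrap and visual
    predictive checks, covariate-corrected subgroup meta-analysis with
    DerSimonian-Laird pooling, and a synthetic aggregate-trial generator
    matching the covariate distributions and variance components of the
    published model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    metafor,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
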