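Package: netgradient
Title: Flexible Excess-Hazard Modelling of Deprivation Gradients in Cancer Net Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying socioeconomic gradients in cancer net survival with
    flexible excess mortality hazard models. Provides registry-like synthetic cohort
    generation with known true excess hazard, background (expected) mortality life
    tables with optional deprivation stratification, restricted cubic spline and
    penalized tensor-product bases with exact curvature penalties, penalized
    full-likelihood estimation of the excess hazard with Laplace approximate
    marginal likelihood (LAML) smoothing selection, corrected-AIC model structure
    selection, prediction of net survival and excess hazard ratios with delta-method
    intervals, the Pohar-Perme non-parametric net survival estimator, model adequacy
    checks, and sensitivity analyses under deprivation-specific life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
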