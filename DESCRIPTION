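Package: gpsdr
Title: Dose-Response Curves for Continuous Treatments via Generalised
    Propensity Scores and Super Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates causal dose-response curves for a positive continuous
    treatment under weak unconfoundedness. The generalised propensity score
    (the conditional density of treatment given covariates) is estimated by a
    Super Learner: a convex combination of candidate conditional-density
    models selected by cross-validated negative log-likelihood. The outcome
    model, either a function of treatment and covariates (regression
    adjustment) or of treatment and the estimated propensity score
    (Hirano-Imbens two-stage adjustment), is a second Super Learner selected
    by cross-validated mean squared error. Provides marginal treatment effect
    curves, nonparametric bootstrap confidence intervals that re-estimate
    both learners per replicate, covariate balance diagnostics by blocking on
    the propensity score within treatment tertiles, common-support
    assessment, and a synthetic-data generator with known dose-response truth
    for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
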