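Package: burnoutprev
Title: Nonresponse-Adjusted Burnout Prevalence Estimation from EHR Use Features
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating population-level physician burnout prevalence
    from voluntary well-being surveys whose nonresponse may be informative.
    Scores the 10-item Professional Fulfillment Index burnout battery, models
    each survey invitation's response propensity with grouped cross-validated
    penalized logistic regression, trains an ensemble of response-propensity
    weighted penalized linear regressions for the burnout score (unweighted,
    1/p and 1-p weighting), calibrates a bias-corrected combination on a
    held-out split of always responders, converts predicted scores to burnout
    probabilities with a logistic (sigmoid) link centered at the validated
    threshold, and combines observed responder prevalence with predicted
    nonresponder prevalence into a population estimate with bootstrap
    confidence intervals. A synthetic cohort generator with configurable
    missing-at-random / missing-not-at-random response mechanisms provides
    ground truth for validation, including a jitter-and-select synthetic
    response-rate-reduction experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
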