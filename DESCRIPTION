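Package: ordadjust
Title: Confounder Adjustment for Ordinal Outcomes via Covariate
    Adjustment and Propensity-Score Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating a binary treatment effect on an ordinal
    (Likert-type) outcome in observational data. Implements weighted
    proportional-odds cumulative logistic regression with analytic
    gradients, propensity-score estimation by gradient boosting with
    stabilized inverse-probability-of-treatment (IPTW) and ATT weights,
    covariate balance diagnostics (standardized mean differences,
    effective sample size, love-plot tables), percentile bootstrap
    confidence intervals for weight-dependent fits, a Monte-Carlo engine
    comparing unadjusted, covariate-adjusted, PS-weighted and combined
    estimators under correctly specified and misspecified generative
    scenarios, and a synthetic vaccine-hesitancy survey generator for
    end-to-end testing of the applied ATT pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
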