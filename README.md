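# ordadjust

Confounder adjustment for ordinal outcomes: covariate adjustment,
propensity-score weighting, and their combination, built on weighted
proportional-odds cumulative logistic regression.

## Who this is for

Analysts of observational surveys — common in health psychology and
epidemiology — where a self-selected binary "treatment" (e.g. accepting
a vaccine) is compared on a Likert-type outcome (e.g. adherence to
protective behaviours), and covariates such as trust, risk perception
and sociodemographics confound the comparison.  The package provides
both a **Monte-Carlo laboratory** for studying how much bias each
adjustment strategy removes (including under model misspecification)
and an **applied ATT pipeline** (propensity weighting, balance
diagnostics, bootstrap intervals) runnable on any suitably shaped
survey table.

## The model and the estimators

The outcome model throughout is the proportional-odds cumulative logit

```
logit P(Y <= j | x) = alpha_j - x' beta ,   j = 1..J-1,
```

with the minus convention of mainstream ordinal-regression software: a
positive slope shifts mass toward higher categories, and the treatment
odds ratio is `OR = exp(beta)`.  Four estimators of the treatment
slope are compared:

* **A** — unadjusted `Y ~ X`;
* **B** — covariate-adjusted `Y ~ X + Z`;
* **C** — `Y ~ X` weighted by stabilized inverse-probability-of-
  treatment weights `WS = p_x / pi_hat` (treated),
  `(1 - p_x)/(1 - pi_hat)` (controls), with the propensity `pi_hat`
  fitted by gradient boosting;
* **D** — weighting and covariate adjustment combined.

The simulation engine draws confounded ordinal data from two
scenarios — `Z ~ U(0,1)`, `X ~ Bern(Z)`, linear predictor
`beta*X + gamma*Z` (correctly specified) or `X ~ Bern(Z^2)` with
`beta*X + gamma*Z^2` (quadratic truth, so linear adjustment is
misspecified) — and scores each method by average relative bias
`ARebias = mean((beta_hat - beta)/beta)` and MSE over K replicates.

The applied pipeline targets the treatment effect **on the treated**
(ATT: treated weight 1, controls weighted by their propensity odds),
composes ATT weights with survey sampling weights, reports
standardized-mean-difference balance and Kish effective sample sizes,
and uses a percentile bootstrap (propensity refitted inside every
resample) for the weighted estimates' intervals.

## Worked example

```r
library(ordadjust)

report <- run_grid(
  simulation_design(1, n = 1000, beta = 0.5, gamma = 1),
  K = 200, methods = c("A", "B", "C", "D"), seed = 1)
report
#> Simulation report: 1 cells x methods, K = 200
#>  scenario    n beta gamma method arebias arebias_se   mse n_replicates n_failures
#>         1 1000  0.5     1      A   0.704      0.015 0.136          200          0
#>         1 1000  0.5     1      B   0.056      0.019 0.018          200          0
#>         1 1000  0.5     1      C   0.120      0.022 0.028          200          0
#>         1 1000  0.5     1      D   0.069      0.024 0.029          200          0
```

The unadjusted estimator (A) overstates the treatment slope by ~70%:
the confounder pushes treated units toward higher categories and the
naive fit credits that to treatment.  Covariate adjustment (B) and the
combined method (D) shrink the relative bias to a few percent, with B
also the most precise (lowest MSE) since its model is exactly the
generating one.

The applied side runs on a synthetic vaccine-hesitancy survey (1468
respondents, 88.7% vaccinated, true OR = 1 with strong confounding
through correlated attitude scores):

```r
survey <- generate_survey(survey_design(n = 1468, seed = 1))
res <- applied_pipeline(
  survey, "mask_use",
  ps_config = propensity_config(n_trees = 200, learning_rate = 0.1,
                                estimand = "ATT",
                                sampling_weights_used = TRUE),
  n_boot = 200, seed = 1)
res
#> Applied ATT pipeline, outcome: mask_use
#>  method       term or_point ci_low ci_high ci_method
#>       A vaccinated     1.86   1.38    2.51      wald
#>       B vaccinated     0.87   0.62    1.22      wald
#>       C vaccinated     1.10   0.67    1.68 bootstrap
#>       D vaccinated     0.92   0.57    1.45 bootstrap
#> Control ESS: 148.2 -> 49.3 after ATT weighting (0 boot failures)
```

The naive model (A) reports a significant OR of 1.86 although the true
effect is null; all three adjusted estimators cover OR = 1.  The control effective sample size drops sharply after ATT
weighting — the price of reweighting a small, very different refuser
group onto the vaccinated covariate profile.

A thin command-line front end wraps the same functions
(`inst/cli/ordadjust`): `simulate`, `synth-survey`, `applied`, and
`balance` subcommands with CSV/YAML input-output and JSON run
manifests.

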