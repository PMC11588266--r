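test_that("the default survey hits the target vaccination prevalence", {
  s <- generate_survey(survey_design(n = 1468, seed = 5))
  expect_equal(mean(s$vaccinated), 0.887, tolerance = 0.02)
  expect_true(all(c("gender", "age_class", "education", "employment",
                    "past_contagion", "chronic_disease", "perceived_risk",
                    "conspiracy", "trust_health_inst", "trust_health_info",
                    "trust_media_info", "freq_health_info", "freq_media_info",
                    "physical_distancing", "mask_use", "hand_disinfection",
                    "vaccinated", "sampling_weight") %in% names(s)))
  expect_true(all(s$mask_use %in% 1:7))
  expect_true(all(s$sampling_weight > 0))
  # identical seed reproduces the table
  expect_identical(s$mask_use, generate_survey(survey_design(n = 1468, seed = 5))$mask_use)
})

test_that("generated factor-score imbalance matches the configured shifts", {
  s <- generate_survey(survey_design(n = 5000, seed = 11))
  shifts <- default_covariate_spec()$continuous
  for (v in names(shifts)) {
    expect_lt(abs(as.numeric(smd(s[[v]], s$vaccinated)) - abs(shifts[[v]])),
              0.05)
  }
})

test_that("prevalence and design validation reject impossible targets", {
  expect_error(survey_design(treated_fraction = 1.1), "\\(0, 1\\)")
  expect_error(survey_design(treated_fraction = 0), "\\(0, 1\\)")
  expect_error(survey_design(n = 1), ">= 2")
})

test_that("no confounding and a null effect give OR ~ 1 for all methods", {
  spec <- default_covariate_spec()
  for (v in names(spec$categorical)) {
    spec$categorical[[v]]$p_control <- spec$categorical[[v]]$p_treated
  }
  spec$continuous[] <- 0
  s <- generate_survey(survey_design(n = 4000, covariate_spec = spec, seed = 21))
  s$.y5 <- recode_outcome(s$mask_use)
  fa <- fit_clm(s, ".y5", "vaccinated", weights = s$sampling_weight)
  fb <- fit_clm(s, ".y5", c("vaccinated", survey_covariates()),
                weights = s$sampling_weight)
  expect_equal(exp(fa$slopes[["vaccinated"]]), 1, tolerance = 0.25)
  expect_equal(exp(fb$slopes[["vaccinated"]]), 1, tolerance = 0.25)
  expect_equal(fa$slopes[["vaccinated"]], fb$slopes[["vaccinated"]],
               tolerance = 0.15)
})

test_that("confounding inflates the naive OR when the true effect is null", {
  s <- generate_survey(survey_design(n = 5000, seed = 31))
  s$.y5 <- recode_outcome(s$hand_disinfection)
  fa <- fit_clm(s, ".y5", "vaccinated", weights = s$sampling_weight)
  fb <- fit_clm(s, ".y5", c("vaccinated", survey_covariates()),
                weights = s$sampling_weight)
  expect_gt(exp(fa$slopes[["vaccinated"]]), 1.25)   # naive OR well above 1
  expect_equal(exp(fb$slopes[["vaccinated"]]), 1, tolerance = 0.2)
})

test_that("the combined ATT estimator recovers configured true ORs", {
  cfg <- propensity_config(n_trees = 200, learning_rate = 0.1,
                           estimand = "ATT", sampling_weights_used = TRUE)
  for (or_true in c(1.0, 1.5)) {
    des <- survey_design(n = 5000,
                         outcome_spec = default_outcome_spec(log(or_true)),
                         seed = 41)
    s <- generate_survey(des)
    s$.y5 <- recode_outcome(s$mask_use)
    ps <- estimate_propensity(s, survey_covariates(), cfg,
                              treatment = "vaccinated",
                              sampling_weights = s$sampling_weight)
    fd <- fit_clm(s, ".y5", c("vaccinated", survey_covariates()),
                  weights = ps$analysis_weights, compute_vcov = FALSE)
    expect_equal(exp(fd$slopes[["vaccinated"]]), or_true,
                 tolerance = 0.1 * or_true)
  }
})

test_that("the applied pipeline emits the four-method effect table with balance", {
  s <- generate_survey(survey_design(n = 1468, seed = 3))
  res <- applied_pipeline(
    s, "mask_use",
    ps_config = propensity_config(100, 0.2, "ATT", TRUE),
    n_boot = 25, seed = 9)
  expect_equal(res$effects$method, c("A", "B", "C", "D"))
  expect_true(all(res$effects$ci_low <= res$effects$ci_high))
  expect_equal(res$effects$ci_method, c("wald", "wald", "bootstrap", "bootstrap"))
  # unadjusted OR inflated, adjusted near 1 (null true effect)
  expect_gt(res$effects$or_point[1], 1.2)
  expect_lt(abs(log(res$effects$or_point[2])), log(1.6))
  # balance improves and control ESS shrinks below the raw control count
  expect_lt(mean(res$balance$smd_after), mean(res$balance$smd_before))
  expect_lt(res$ess["control"], sum(s$vaccinated == 0))
  expect_lte(res$n_boot_failures, 2)
})
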