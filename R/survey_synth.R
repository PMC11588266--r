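#' Default confounding structure of the synthetic vaccine survey
#'
#' Returns the per-covariate specification used by [survey_design()]:
#' six categorical sociodemographic variables with group-specific level
#' probabilities and seven standardized continuous factor scores with
#' group mean-shifts.  The shift of a unit-variance Gaussian score *is*
#' its standardized mean difference, so these values directly set the
#' covariate imbalance between vaccinated and refusing respondents
#' (strong imbalance on the trust/conspiracy scores, mild imbalance on
#' demographics).
#'
#' The scores are not independent: each loads on a single latent
#' "vaccine attitude" factor whose group-difference is `latent_smd`,
#' with loading `shift / latent_smd`, plus independent unique noise.
#' This mimics real survey factor scores (trust, risk perception and
#' conspiracy beliefs are strongly inter-correlated) and keeps the
#' joint treated/control overlap realistic: with independent scores the
#' compound separation across seven shifted covariates would violate
#' positivity far more severely than observed survey data do.  Each
#' score remains unit-variance within group with exactly its configured
#' marginal SMD.
#'
#' Because both groups are Gaussian with equal covariance, drawing
#' treatment first and scores conditional on group is exactly
#' equivalent to a logistic treatment-assignment model on the scores,
#' calibrated to the target prevalence.
#'
#' @return A list with elements `categorical` (per-variable list of
#'   `levels`, `p_control`, `p_treated`) and `continuous` (named vector
#'   of treated-minus-control mean shifts).
#' @export
default_covariate_spec <- function() {
  list(
    categorical = list(
      gender = list(levels = c("female", "male"),
                    p_control = c(0.512, 0.488),
                    p_treated = c(0.495, 0.505)),
      age_class = list(levels = c("18-34", "35-44", "45-54", "55-70"),
                       p_control = c(0.133, 0.163, 0.295, 0.409),
                       p_treated = c(0.144, 0.125, 0.258, 0.473)),
      education = list(levels = c("0-8y", "9-13y", "13y+"),
                       p_control = c(0.428, 0.386, 0.186),
                       p_treated = c(0.303, 0.409, 0.288)),
      employment = list(levels = c("unemployed", "employed_other",
                                   "employed_health"),
                        p_control = c(0.422, 0.536, 0.042),
                        p_treated = c(0.452, 0.443, 0.105)),
      past_contagion = list(levels = c("no", "dont_know", "yes"),
                            p_control = c(0.741, 0.145, 0.114),
                            p_treated = c(0.855, 0.042, 0.103)),
      chronic_disease = list(levels = c("no", "dont_know", "yes"),
                             p_control = c(0.590, 0.084, 0.326),
                             p_treated = c(0.644, 0.036, 0.320))
    ),
    continuous = c(perceived_risk = 0.28,
                   conspiracy = -0.48,
                   trust_health_inst = 0.75,
                   trust_health_info = 0.84,
                   trust_media_info = 0.42,
                   freq_health_info = 0.75,
                   freq_media_info = 0.30),
    latent_smd = 1.0
  )
}

#' Default outcome models of the synthetic survey
#'
#' Three 7-point Likert outcomes (physical distancing, mask use, hand
#' disinfection) generated from cumulative logit models.  The true
#' treatment log odds ratio defaults to 0 (OR = 1: vaccination has no
#' causal effect on adherence), while the factor scores carry outcome
#' effects of magnitude 0.25 signed like their group shifts, so the
#' *unadjusted* treated-vs-control OR exceeds 1 by confounding alone.
#' Baseline category probabilities are bottom-sparse, mimicking
#' adherence scales where most respondents answer 5-7.
#'
#' @param true_log_or Named or scalar true treatment log-OR(s) for the
#'   three outcomes (default 0).
#' @return A list with `outcomes` (per-outcome `baseline_probs` and
#'   `true_log_or`) and `score_effects` (named coefficients of the
#'   factor scores in every outcome model).
#' @export
default_outcome_spec <- function(true_log_or = 0) {
  nm <- c("physical_distancing", "mask_use", "hand_disinfection")
  tl <- rep(true_log_or, length.out = 3L)
  if (!is.null(names(true_log_or))) {
    tl <- setNames(rep(0, 3L), nm)
    tl[names(true_log_or)] <- true_log_or
  }
  baselines <- list(
    physical_distancing = c(0.022, 0.025, 0.030, 0.121, 0.231, 0.251, 0.320),
    mask_use = c(0.005, 0.005, 0.016, 0.031, 0.134, 0.219, 0.590),
    hand_disinfection = c(0.007, 0.011, 0.022, 0.053, 0.130, 0.210, 0.567)
  )
  outcomes <- lapply(seq_along(nm), function(i) {
    bp <- baselines[[nm[i]]]
    list(baseline_probs = bp / sum(bp), true_log_or = unname(tl[i]))
  })
  names(outcomes) <- nm
  list(outcomes = outcomes,
       score_effects = c(perceived_risk = 0.25,
                         conspiracy = -0.25,
                         trust_health_inst = 0.25,
                         trust_health_info = 0.25,
                         trust_media_info = 0.25,
                         freq_health_info = 0.25,
                         freq_media_info = 0.25))
}

#' Design of a synthetic vaccine-hesitancy survey
#'
#' @param n Number of respondents (default 1468).
#' @param treated_fraction Target vaccination prevalence in (0, 1)
#'   (default 0.887).
#' @param covariate_spec See [default_covariate_spec()].
#' @param outcome_spec See [default_outcome_spec()].
#' @param sampling_weight_spec List with `meanlog`/`sdlog` of the
#'   log-normal sampling-weight distribution (normalized to mean 1).
#' @param seed Integer seed.
#' @return An object of class `"survey_design"`.
#' @export
survey_design <- function(n = 1468L, treated_fraction = 0.887,
                          covariate_spec = default_covariate_spec(),
                          outcome_spec = default_outcome_spec(),
                          sampling_weight_spec = list(meanlog = 0, sdlog = 0.35),
                          seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (!is.numeric(treated_fraction) || treated_fraction <= 0 ||
      treated_fraction >= 1) {
    stop("`treated_fraction` must be in (0, 1)", call. = FALSE)
  }
  for (cv in covariate_spec$categorical) {
    stopifnot(length(cv$levels) == length(cv$p_control),
              length(cv$levels) == length(cv$p_treated),
              all(cv$p_control > 0), all(cv$p_treated > 0))
  }
  for (oc in outcome_spec$outcomes) .check_prob_vector(oc$baseline_probs)
  structure(list(n = n, treated_fraction = treated_fraction,
                 covariate_spec = covariate_spec,
                 outcome_spec = outcome_spec,
                 sampling_weight_spec = sampling_weight_spec,
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Generate a synthetic vaccine-hesitancy survey
#'
#' Emits one row per respondent: vaccination status (drawn at the
#' target prevalence), six categorical sociodemographics and seven
#' standardized factor scores drawn conditional on vaccination group
#' (which by Bayes' rule is a logistic assignment model on the
#' covariates), three 7-point ordinal adherence outcomes from
#' cumulative logit models with the configured true treatment effect,
#' and a positive sampling weight.  With the default spec the true
#' treatment OR is 1 while confounding pushes the naive OR above 1.
#'
#' @param design A [survey_design()].
#' @return A data frame of class `"synthetic_survey"`.
#' @export
#' @examples
#' s <- generate_survey(survey_design(n = 300, seed = 5))
#' mean(s$vaccinated)
generate_survey <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(design$seed)

  n <- design$n
  p <- design$treated_fraction
  x <- rbinom(n, 1L, p)
  if (sum(x) == 0L || sum(x) == n) {  # tiny-n guard: both groups required
    x[sample.int(n, 1L)] <- 1L - x[1L]
  }
  out <- data.frame(vaccinated = x)

  for (vn in names(design$covariate_spec$categorical)) {
    cv <- design$covariate_spec$categorical[[vn]]
    pc <- cv$p_control / sum(cv$p_control)
    pt <- cv$p_treated / sum(cv$p_treated)
    draw <- character(n)
    draw[x == 0] <- sample(cv$levels, sum(x == 0), TRUE, pc)
    draw[x == 1] <- sample(cv$levels, sum(x == 1), TRUE, pt)
    out[[vn]] <- factor(draw, levels = cv$levels)
  }
  shifts <- design$covariate_spec$continuous
  latent_smd <- design$covariate_spec$latent_smd
  if (is.null(latent_smd)) latent_smd <- max(abs(shifts), 1e-8)
  if (max(abs(shifts)) > latent_smd + 1e-12) {
    stop("latent_smd must be at least the largest absolute score shift",
         call. = FALSE)
  }
  # shared latent attitude factor; centered so the marginal mean is ~0,
  # group difference = latent_smd (both groups have unit variance)
  a <- rnorm(n, mean = ifelse(x == 1, (1 - p), -p) * latent_smd, sd = 1)
  for (vn in names(shifts)) {
    lambda <- shifts[[vn]] / latent_smd   # marginal group SMD = shifts[vn]
    out[[vn]] <- lambda * a + sqrt(1 - lambda^2) * rnorm(n)
  }

  eff <- design$outcome_spec$score_effects
  eta_conf <- as.matrix(out[names(eff)]) %*% eff
  for (on in names(design$outcome_spec$outcomes)) {
    oc <- design$outcome_spec$outcomes[[on]]
    eta <- oc$true_log_or * x + drop(eta_conf)
    probs <- category_probs(derive_intercepts(oc$baseline_probs), eta)
    out[[on]] <- .sample_categories(probs)
  }

  sw <- rlnorm(n, design$sampling_weight_spec$meanlog,
               design$sampling_weight_spec$sdlog)
  out$sampling_weight <- sw / mean(sw)

  attr(out, "design") <- design
  class(out) <- c("synthetic_survey", "data.frame")
  out
}

#' Covariate terms of the applied survey models
#'
#' The adjustment set of the applied analysis: all sociodemographics,
#' past contagion, chronic disease, the seven factor scores, and the
#' gender interactions with age class, education, perceived risk and
#' conspiracy.  The same terms feed the propensity model and the
#' covariate-adjusted cumulative logit.
#'
#' @param interactions Include the gender interaction terms?
#' @return Character vector of model terms.
#' @export
survey_covariates <- function(interactions = TRUE) {
  base <- c("gender", "age_class", "education", "employment",
            "past_contagion", "chronic_disease",
            "perceived_risk", "conspiracy", "trust_health_inst",
            "trust_health_info", "trust_media_info",
            "freq_health_info", "freq_media_info")
  if (interactions) {
    base <- c(base, "gender:age_class", "gender:education",
              "gender:perceived_risk", "gender:conspiracy")
  }
  base
}

#' Applied ATT estimation pipeline on a survey table
#'
#' Reproduces the survey workflow end-to-end for one adherence outcome:
#' recodes the 7-point outcome to 5 categories, then estimates the
#' vaccination odds ratio by
#'
#' * **A** — sampling-weighted cumulative logit, treatment only
#'   (Wald CI);
#' * **B** — adds the covariate set and gender interactions (Wald CI);
#' * **C** — ATT weights from a gradient-boosted propensity model
#'   (times sampling weights), treatment-only cumulative logit
#'   (percentile bootstrap CI);
#' * **D** — ATT weights plus covariate adjustment (bootstrap CI).
#'
#' Bootstrap replicates resample rows and re-run propensity fitting,
#' weighting and the weighted fits; methods C and D share each
#' replicate's propensity fit.
#'
#' @param survey A survey table (e.g. from [generate_survey()]) with a
#'   `vaccinated` 0/1 column and `sampling_weight`.
#' @param outcome Name of the 7-point outcome column.
#' @param covariates Model terms (default [survey_covariates()]).
#' @param ps_config [propensity_config()]; default 10000 trees,
#'   learning rate 0.01, ATT, sampling weights in the fit.
#' @param n_boot Bootstrap replications for methods C/D (default 500).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `"applied_result"`: list with `effects`
#'   (4-row data frame: `method`, `term`, `or_point`, `ci_low`,
#'   `ci_high`, `ci_method`), `balance` (SMD table before/after ATT
#'   weighting), `ess` (named: control/treated, after weighting),
#'   `ess_before`, `n_boot_failures`.
#' @export
applied_pipeline <- function(survey, outcome,
                             covariates = survey_covariates(),
                             ps_config = propensity_config(
                               n_trees = 10000L, learning_rate = 0.01,
                               estimand = "ATT",
                               sampling_weights_used = TRUE),
                             n_boot = 500L, level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(survey), outcome %in% names(survey),
            all(c("vaccinated", "sampling_weight") %in% names(survey)))
  dat <- as.data.frame(survey)
  dat$.y5 <- recode_outcome(dat[[outcome]])
  sw <- dat$sampling_weight

  fitA <- fit_clm(dat, ".y5", "vaccinated", weights = sw)
  fitB <- fit_clm(dat, ".y5", c("vaccinated", covariates), weights = sw)
  estA <- wald_ci(fitA, "vaccinated", level)
  estB <- wald_ci(fitB, "vaccinated", level)

  ps <- estimate_propensity(dat, covariates, ps_config,
                            treatment = "vaccinated",
                            sampling_weights = sw)

  fitC0 <- fit_clm(dat, ".y5", "vaccinated", weights = ps$analysis_weights,
                   compute_vcov = FALSE)
  fitD0 <- fit_clm(dat, ".y5", c("vaccinated", covariates),
                   weights = ps$analysis_weights, compute_vcov = FALSE)

  # shared-resample bootstrap for C and D, warm-started at the full fits
  cd_estimator <- function(d) {
    d_sw <- d$sampling_weight
    pi_hat <- fit_propensity(d, covariates, ps_config,
                             treatment = "vaccinated",
                             sampling_weights = d_sw)
    aw <- att_weights(pi_hat, d$vaccinated, ps_config$clip) * d_sw
    fc <- fit_clm(d, ".y5", "vaccinated", weights = aw, start = fitC0,
                  compute_vcov = FALSE)
    fd <- fit_clm(d, ".y5", c("vaccinated", covariates), weights = aw,
                  start = fitD0, compute_vcov = FALSE)
    if (!fc$converged || !fd$converged) stop("non-converged replicate")
    c(C = fc$slopes[["vaccinated"]], D = fd$slopes[["vaccinated"]])
  }
  estCD <- bootstrap_ci(dat, cd_estimator, n_boot = n_boot, level = level,
                        seed = seed)

  effects <- rbind(
    cbind(method = "A", estA),
    cbind(method = "B", estB),
    cbind(method = c("C", "D"),
          data.frame(term = "vaccinated",
                     or_point = estCD$or_point,
                     ci_low = estCD$ci_low, ci_high = estCD$ci_high,
                     ci_method = estCD$ci_method,
                     stringsAsFactors = FALSE))
  )
  rownames(effects) <- NULL

  structure(
    list(effects = effects,
         balance = ps$smd_table,
         ess = ps$ess_by_group,
         ess_before = c(
           control = effective_sample_size(sw[dat$vaccinated == 0]),
           treated = effective_sample_size(sw[dat$vaccinated == 1])),
         n_boot_failures = attr(estCD, "n_failures"),
         outcome = outcome),
    class = "applied_result"
  )
}

#' @export
print.applied_result <- function(x, ...) {
  cat(sprintf("Applied ATT pipeline, outcome: %s\n", x$outcome))
  eff <- x$effects
  eff$or_point <- round(eff$or_point, 2)
  eff$ci_low <- round(eff$ci_low, 2)
  eff$ci_high <- round(eff$ci_high, 2)
  print.data.frame(eff, row.names = FALSE)
  cat(sprintf("Control ESS: %.1f -> %.1f after ATT weighting (%d boot failures)\n",
              x$ess_before["control"], x$ess["control"], x$n_boot_failures))
  invisible(x)
}
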