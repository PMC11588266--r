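#' Configuration for propensity-score estimation
#'
#' @param n_trees Number of boosting iterations (default 200, the
#'   simulation-study setting; the applied survey analysis uses 10000).
#' @param learning_rate Shrinkage per tree (default 0.1; applied
#'   analysis uses 0.01).
#' @param estimand `"ATE_stabilized"` (stabilized IPTW over the full
#'   population) or `"ATT"` (treated weight 1, controls weighted to the
#'   treated covariate distribution).
#' @param sampling_weights_used Should unit sampling weights enter the
#'   boosting fit (survey setting)?
#' @param clip Optional length-2 vector of probability bounds inside
#'   (0, 1) applied to fitted propensities before weighting; `NULL`
#'   (default) leaves probabilities untruncated.
#' @param seed Integer seed recorded with the config (the boosting fit
#'   itself is deterministic: depth-3 trees, no subsampling, one
#'   thread).
#' @return An object of class `"propensity_config"`.
#' @export
propensity_config <- function(n_trees = 200L, learning_rate = 0.1,
                              estimand = c("ATE_stabilized", "ATT"),
                              sampling_weights_used = FALSE,
                              clip = NULL, seed = 1L) {
  estimand <- match.arg(estimand)
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be >= 1", call. = FALSE)
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate > 1) {
    stop("`learning_rate` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] < clip[2])
    if (clip[1] <= 0 || clip[2] >= 1) stop("`clip` bounds must lie inside (0, 1)", call. = FALSE)
  }
  structure(list(n_trees = n_trees, learning_rate = learning_rate,
                 estimand = estimand,
                 sampling_weights_used = isTRUE(sampling_weights_used),
                 clip = clip, seed = as.integer(seed)),
            class = "propensity_config")
}

#' Gradient-boosted propensity scores
#'
#' Fits the probability of treatment given covariates with a gradient
#' boosted tree ensemble (logistic loss, depth-3 trees, no subsampling,
#' deterministic single-thread fit), the flexible default of the
#' PS-weighting literature: unlike a linear logistic model it adapts to
#' nonlinear treatment-assignment mechanisms such as a quadratic
#' confounder effect.
#'
#' @param data Data frame containing the treatment and covariate
#'   columns.
#' @param covariates Character vector of covariate terms (column names;
#'   interactions like `"gender:age_class"` are expanded via the model
#'   matrix).
#' @param config A [propensity_config()].
#' @param treatment Name of the binary 0/1 treatment column (default
#'   `"x"`).
#' @param sampling_weights Optional positive unit weights entering the
#'   boosting fit when `config$sampling_weights_used` is `TRUE`.
#' @return Numeric vector of fitted treatment probabilities in (0, 1).
#' @export
fit_propensity <- function(data, covariates, config = propensity_config(),
                           treatment = "x", sampling_weights = NULL) {
  stopifnot(inherits(config, "propensity_config"),
            is.data.frame(data), treatment %in% names(data))
  x <- data[[treatment]]
  if (anyNA(x) || !all(x %in% c(0, 1))) stop("treatment must be 0/1", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("treatment has a single class; propensity model is not identified",
         call. = FALSE)
  }
  mm <- model.matrix(reformulate(covariates), data = data)
  X <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  const <- apply(X, 2L, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    warning("constant covariate column(s) in propensity model: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  w <- if (config$sampling_weights_used && !is.null(sampling_weights)) {
    stopifnot(length(sampling_weights) == nrow(X), all(sampling_weights > 0))
    as.numeric(sampling_weights)
  } else NULL

  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(x), weight = w,
                                 nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = 3L,
                  eta = config$learning_rate,
                  min_child_weight = 10,  # classic GBM node-size default
                  subsample = 1,
                  colsample_bytree = 1,
                  nthread = 1L,
                  seed = config$seed),
    data = dtrain, nrounds = config$n_trees, verbose = 0)
  pi_hat <- predict(booster, dtrain)
  if (!is.null(config$clip)) {
    pi_hat <- pmin(pmax(pi_hat, config$clip[1]), config$clip[2])
  }
  pi_hat
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `WS_i = p_x / pi_hat_i` for treated units and
#' `(1 - p_x) / (1 - pi_hat_i)` for controls, where `p_x` is the
#' observed treated proportion.  Multiplying the inverse-probability
#' weight by the marginal treatment probability keeps the mean weight
#' near 1 in each group and reduces weight variance.
#'
#' @param pi_hat Fitted treatment probabilities in (0, 1).
#' @param x Binary 0/1 treatment vector.
#' @param clip Optional probability bounds applied to `pi_hat` first.
#' @return Positive weight vector of the same length.
#' @export
stabilized_weights <- function(pi_hat, x, clip = NULL) {
  .check_pi(pi_hat, x, clip)
  if (!is.null(clip)) pi_hat <- pmin(pmax(pi_hat, clip[1]), clip[2])
  if (any(pi_hat <= 0 | pi_hat >= 1)) {
    stop("fitted probabilities at 0 or 1; set `clip` to proceed", call. = FALSE)
  }
  p_x <- mean(x)
  ifelse(x == 1, p_x / pi_hat, (1 - p_x) / (1 - pi_hat))
}

#' Weights targeting the average treatment effect on the treated (ATT)
#'
#' Treated units keep weight 1; each control is weighted by its
#' propensity odds `pi_hat / (1 - pi_hat)`, which reweights the control
#' group to the covariate distribution of the treated.
#'
#' @inheritParams stabilized_weights
#' @return Positive weight vector; all treated weights are exactly 1.
#' @export
att_weights <- function(pi_hat, x, clip = NULL) {
  .check_pi(pi_hat, x, clip)
  if (!is.null(clip)) pi_hat <- pmin(pmax(pi_hat, clip[1]), clip[2])
  if (any(pi_hat[x == 0] >= 1)) {
    stop("control unit with fitted probability 1; set `clip` to proceed",
         call. = FALSE)
  }
  ifelse(x == 1, 1, pi_hat / (1 - pi_hat))
}

.check_pi <- function(pi_hat, x, clip) {
  stopifnot(is.numeric(pi_hat), length(pi_hat) == length(x))
  if (anyNA(pi_hat) || any(pi_hat < 0 | pi_hat > 1)) {
    stop("`pi_hat` must be probabilities", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) stop("`x` must be 0/1", call. = FALSE)
  if (!is.null(clip) && (length(clip) != 2L || clip[1] <= 0 || clip[2] >= 1)) {
    stop("`clip` must be two bounds inside (0, 1)", call. = FALSE)
  }
}

#' Standardized mean difference between treatment groups
#'
#' For a numeric covariate:
#' `|m1 - m0| / sqrt((s1^2 + s0^2) / 2)` with (optionally weighted)
#' group means and variances.  For a factor, the SMD is computed per
#' level indicator and the maximum over levels is returned (per-level
#' values are in `attr(, "levels")`).
#'
#' @param values Numeric vector or factor.
#' @param x Binary 0/1 group indicator.
#' @param weights Optional positive weights; `NULL` gives the unweighted
#'   ("before") SMD.
#' @return A single nonnegative number.
#' @export
smd <- function(values, x, weights = NULL) {
  stopifnot(length(values) == length(x), all(x %in% c(0, 1)))
  if (sum(x == 1) == 0L || sum(x == 0) == 0L) {
    stop("both treatment groups must be non-empty", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  stopifnot(all(w > 0), length(w) == length(x))
  if (is.factor(values) || is.character(values)) {
    f <- factor(values)
    per_level <- vapply(levels(f), function(lv) {
      .smd_numeric(as.numeric(f == lv), x, w)
    }, 0)
    return(structure(max(per_level), levels = per_level))
  }
  .smd_numeric(as.numeric(values), x, w)
}

.smd_numeric <- function(v, x, w) {
  m1 <- .wmean(v[x == 1], w[x == 1]); m0 <- .wmean(v[x == 0], w[x == 0])
  s1 <- .wvar(v[x == 1], w[x == 1]);  s0 <- .wvar(v[x == 0], w[x == 0])
  pooled <- sqrt((s1 + s0) / 2)
  if (pooled == 0) {
    if (abs(m1 - m0) < 1e-12) return(0)
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  abs(m1 - m0) / pooled
}

.wmean <- function(v, w) sum(w * v) / sum(w)

.wvar <- function(v, w) {
  m <- .wmean(v, w)
  sum(w * (v - m)^2) / sum(w)
}

#' Kish effective sample size of a weighted sample
#'
#' `ESS = (sum w)^2 / sum(w^2)`; equals `n` iff all weights are equal
#' and decreases as the weights become more variable.
#'
#' @param weights Positive weight vector.
#' @return A number in (0, `length(weights)`\].
#' @export
effective_sample_size <- function(weights) {
  if (length(weights) == 0L) stop("empty weight vector", call. = FALSE)
  stopifnot(is.numeric(weights), all(weights > 0), all(is.finite(weights)))
  sum(weights)^2 / sum(weights^2)
}

#' Covariate balance table before and after weighting
#'
#' Computes the SMD of each covariate between treatment groups on the
#' base sample (optionally sampling-weighted, the survey "before"
#' state) and on the weighted sample.
#'
#' @param data Data frame with the covariate and treatment columns.
#' @param covariates Character vector of covariate column names.
#' @param treatment Name of the 0/1 treatment column.
#' @param weights Analysis weights (e.g. sampling x ATT) defining the
#'   "after" state.
#' @param base_weights Optional weights defining the "before" state
#'   (default unweighted).
#' @return Data frame with columns `covariate`, `smd_before`,
#'   `smd_after`.
#' @export
balance_table <- function(data, covariates, treatment = "x", weights,
                          base_weights = NULL) {
  x <- data[[treatment]]
  out <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v)
      as.numeric(smd(data[[v]], x, base_weights)), 0),
    smd_after = vapply(covariates, function(v)
      as.numeric(smd(data[[v]], x, weights)), 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Long-format love-plot data
#'
#' Stacks before/after SMDs into the tidy layout used for love plots,
#' sorted by unweighted SMD (descending), with the effective sample
#' sizes carried as attributes.
#'
#' @param smd_before,smd_after Data frames with columns `covariate` and
#'   `smd` (or the output columns of [balance_table()]), covering the
#'   same covariate set.
#' @param ess_before,ess_after Optional ESS annotations.
#' @return Data frame with columns `covariate`, `phase`
#'   (`"unweighted"`/`"weighted"`), `smd`; attributes `ess_before`,
#'   `ess_after`.
#' @export
love_plot_table <- function(smd_before, smd_after,
                            ess_before = NA_real_, ess_after = NA_real_) {
  gb <- .as_smd_frame(smd_before, c("smd_before", "smd"))
  ga <- .as_smd_frame(smd_after, c("smd_after", "smd"))
  if (!setequal(gb$covariate, ga$covariate)) {
    stop("covariate sets of before/after tables differ", call. = FALSE)
  }
  ord <- order(gb$smd, decreasing = TRUE)
  gb <- gb[ord, , drop = FALSE]
  ga <- ga[match(gb$covariate, ga$covariate), , drop = FALSE]
  out <- data.frame(
    covariate = rep(gb$covariate, each = 2L),
    phase = rep(c("unweighted", "weighted"), times = nrow(gb)),
    smd = as.vector(rbind(gb$smd, ga$smd)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "ess_before") <- ess_before
  attr(out, "ess_after") <- ess_after
  out
}

.as_smd_frame <- function(tab, candidates) {
  stopifnot(is.data.frame(tab), "covariate" %in% names(tab))
  col <- intersect(candidates, names(tab))[1]
  if (is.na(col)) stop("no SMD column found", call. = FALSE)
  data.frame(covariate = tab$covariate, smd = tab[[col]],
             stringsAsFactors = FALSE)
}

#' Propensity estimation with weights and balance in one step
#'
#' Convenience wrapper running [fit_propensity()], the weight
#' construction matching `config$estimand`, [balance_table()] and
#' group-wise [effective_sample_size()].
#'
#' @inheritParams fit_propensity
#' @return An object of class `"propensity_result"`: list with
#'   `pi_hat`, `weights` (propensity weights only), `analysis_weights`
#'   (times sampling weights, if supplied), `p_x`, `ess_by_group`
#'   (named: control, treated), `smd_table`, `estimand`.
#' @export
estimate_propensity <- function(data, covariates,
                                config = propensity_config(),
                                treatment = "x", sampling_weights = NULL) {
  x <- data[[treatment]]
  pi_hat <- fit_propensity(data, covariates, config, treatment,
                           sampling_weights)
  pw <- switch(config$estimand,
               ATE_stabilized = stabilized_weights(pi_hat, x, config$clip),
               ATT = att_weights(pi_hat, x, config$clip))
  sw <- if (is.null(sampling_weights)) rep(1, length(x)) else sampling_weights
  aw <- pw * sw
  # balance is reported per covariate column; interaction terms enter the
  # boosting model only through the model matrix
  smd_covs <- intersect(covariates, names(data))
  smd_table <- balance_table(data, smd_covs, treatment, weights = aw,
                             base_weights = if (is.null(sampling_weights)) NULL else sw)
  structure(
    list(pi_hat = pi_hat, weights = pw, analysis_weights = aw,
         p_x = mean(x),
         ess_by_group = c(control = effective_sample_size(aw[x == 0]),
                          treated = effective_sample_size(aw[x == 1])),
         smd_table = smd_table,
         estimand = config$estimand),
    class = "propensity_result"
  )
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("Propensity result (%s): p_x = %.3f\n", x$estimand, x$p_x))
  cat(sprintf("ESS control %.1f, treated %.1f\n",
              x$ess_by_group["control"], x$ess_by_group["treated"]))
  cat(sprintf("max |SMD| before %.3f -> after %.3f\n",
              max(x$smd_table$smd_before), max(x$smd_table$smd_after)))
  invisible(x)
}
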