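#' The four estimation strategies compared in the simulation study
#'
#' * **A** — cumulative logit `Y ~ X`, no adjustment;
#' * **B** — cumulative logit `Y ~ X + Z`, covariate adjustment;
#' * **C** — cumulative logit `Y ~ X` with stabilized GBM-IPTW weights;
#' * **D** — cumulative logit `Y ~ X + Z` with stabilized GBM-IPTW
#'   weights (weighting and adjustment combined).
#'
#' @param id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A list with `id`, `uses_covariate`, `uses_ps_weights`.
#' @export
method_spec <- function(id = c("A", "B", "C", "D")) {
  id <- match.arg(id)
  list(id = id,
       uses_covariate = id %in% c("B", "D"),
       uses_ps_weights = id %in% c("C", "D"))
}

#' Estimate the treatment slope by one of methods A-D
#'
#' @param data An ordinal dataset with columns `y`, `x`, `z`.
#' @param method A [method_spec()] or its id letter.
#' @param ps_config [propensity_config()] for methods C/D (200 trees,
#'   learning rate 0.1 by default, as in the simulation study).
#' @param pi_hat Optional fixed treatment probabilities to use instead
#'   of fitting the boosting model (e.g. the true assignment
#'   probabilities, for oracle-weight checks).
#' @return The estimated treatment log odds ratio (numeric scalar).
#'   Errors if the cumulative logit fit does not converge.
#' @export
estimate_beta <- function(data, method, ps_config = propensity_config(),
                          pi_hat = NULL) {
  if (is.character(method)) method <- method_spec(method)
  weights <- NULL
  if (method$uses_ps_weights) {
    if (is.null(pi_hat)) {
      pi_hat <- fit_propensity(data, covariates = "z", config = ps_config)
    }
    weights <- stabilized_weights(pi_hat, data$x, clip = ps_config$clip)
  }
  terms <- if (method$uses_covariate) c("x", "z") else "x"
  fit <- fit_clm(data, "y", terms, weights = weights, compute_vcov = FALSE)
  if (!fit$converged) stop("cumulative logit fit did not converge", call. = FALSE)
  fit$slopes[["x"]]
}

#' Average relative bias of a set of estimates
#'
#' `ARebias = mean((beta_hat_k - beta_true) / beta_true)`, with its
#' Monte-Carlo standard error `sd(relative errors) / sqrt(K)`.
#'
#' @param beta_hats Numeric vector of replicate estimates.
#' @param beta_true True (nonzero) parameter value.
#' @return Named numeric: `arebias`, `se` (`NA` for a single
#'   replicate).
#' @export
arebias <- function(beta_hats, beta_true) {
  if (!is.numeric(beta_true) || beta_true == 0) {
    stop("`beta_true` must be nonzero", call. = FALSE)
  }
  if (length(beta_hats) == 0L) stop("no estimates supplied", call. = FALSE)
  rel <- (beta_hats - beta_true) / beta_true
  se <- if (length(rel) >= 2L) sd(rel) / sqrt(length(rel)) else NA_real_
  c(arebias = mean(rel), se = se)
}

#' Mean squared error of a set of estimates
#'
#' @inheritParams arebias
#' @return `mean((beta_hats - beta_true)^2)`.
#' @export
mse <- function(beta_hats, beta_true) {
  if (length(beta_hats) == 0L) stop("no estimates supplied", call. = FALSE)
  mean((beta_hats - beta_true)^2)
}

#' Monte-Carlo comparison of methods A-D over a design grid
#'
#' For each design cell, draws `K` replicate datasets, estimates the
#' treatment slope with each requested method, and aggregates average
#' relative bias (with Monte-Carlo standard error) and MSE.  Replicates
#' whose fit fails are dropped and counted.  Replicate seeds are derived
#' deterministically from the root seed and the cell index, so the
#' report is reproducible irrespective of execution order.
#'
#' @param designs A [simulation_design()] or list of them.
#' @param K Replicates per cell.
#' @param methods Character vector among `"A","B","C","D"`.
#' @param ps_config [propensity_config()] used by methods C/D.
#' @param seed Root seed; overrides the seeds stored in the designs.
#' @param progress Print a line per completed cell?
#' @return A data frame of class `"simulation_report"` with one row per
#'   cell x method: `scenario`, `n`, `beta`, `gamma`, `method`,
#'   `arebias`, `arebias_se`, `mse`, `n_replicates`, `n_failures`.
#' @export
#' @examples
#' rep <- run_grid(simulation_design(1, 200, 0.5, 1), K = 20,
#'                 methods = c("A", "B"), seed = 1)
#' rep
run_grid <- function(designs, K, methods = c("A", "B", "C", "D"),
                     ps_config = propensity_config(), seed = 1L,
                     progress = FALSE) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be >= 1", call. = FALSE)
  methods <- match.arg(methods, c("A", "B", "C", "D"), several.ok = TRUE)

  rows <- list()
  for (ci in seq_along(designs)) {
    des <- designs[[ci]]
    cell_seed <- .substream_seed(seed, 7919L * ci)
    est <- matrix(NA_real_, K, length(methods),
                  dimnames = list(NULL, methods))
    for (k in seq_len(K)) {
      des_k <- des
      des_k$seed <- .substream_seed(cell_seed, k)
      dat <- simulate_dataset(des_k)
      pi_hat <- NULL
      if (any(c("C", "D") %in% methods)) {
        pi_hat <- try(fit_propensity(dat, "z", ps_config), silent = TRUE)
        if (inherits(pi_hat, "try-error")) pi_hat <- NULL
      }
      for (m in methods) {
        needs_ps <- m %in% c("C", "D")
        if (needs_ps && is.null(pi_hat)) next
        b <- try(estimate_beta(dat, m, ps_config,
                               pi_hat = if (needs_ps) pi_hat else NULL),
                 silent = TRUE)
        if (!inherits(b, "try-error")) est[k, m] <- b
      }
    }
    for (m in methods) {
      ok <- est[!is.na(est[, m]), m]
      if (length(ok) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = des$scenario, n = des$n, beta = des$beta,
          gamma = des$gamma, method = m,
          arebias = NA_real_, arebias_se = NA_real_, mse = NA_real_,
          n_replicates = 0L, n_failures = K, stringsAsFactors = FALSE)
        next
      }
      ab <- arebias(ok, des$beta)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = des$scenario, n = des$n, beta = des$beta,
        gamma = des$gamma, method = m,
        arebias = unname(ab["arebias"]),
        arebias_se = unname(ab["se"]),
        mse = mse(ok, des$beta),
        n_replicates = length(ok), n_failures = K - length(ok),
        stringsAsFactors = FALSE)
    }
    if (progress) {
      message(sprintf("cell %d/%d done (scenario %d, n=%d, beta=%g, gamma=%g)",
                      ci, length(designs), des$scenario, des$n, des$beta,
                      des$gamma))
    }
  }
  report <- do.call(rbind, rows)
  report <- report[order(report$scenario, report$n, report$beta,
                         report$gamma, report$method), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "K") <- K
  attr(report, "seed") <- as.integer(seed)
  class(report) <- c("simulation_report", "data.frame")
  report
}

#' @export
print.simulation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation report: %d cells x methods, K = %s\n",
              nrow(unique(as.data.frame(x)[c("scenario", "n", "beta", "gamma")])),
              attr(x, "K")))
  y <- as.data.frame(x)
  y$arebias <- round(y$arebias, digits)
  y$arebias_se <- round(y$arebias_se, digits)
  y$mse <- round(y$mse, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
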