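#' Weighted proportional-odds cumulative logistic regression
#'
#' Maximizes the weighted multinomial log-likelihood
#' \deqn{\ell(\alpha, \beta) = \sum_i w_i \log P(Y_i = y_i \mid x_i)}
#' under the cumulative logit model
#' `logit P(Y <= j | x) = alpha_j - x' beta` (minus convention: positive
#' slopes shift mass toward higher categories).  Optimization is
#' quasi-Newton (BFGS) with the analytic gradient; threshold
#' monotonicity is enforced by reparameterization (first threshold free,
#' increments log-parameterized), so every iterate is a valid model.
#' The line search only accepts steps that increase the log-likelihood,
#' and the iteration trace is stored in the fit.
#'
#' The covariance is the inverse observed information at the optimum in
#' the natural `(alpha, beta)` parameterization.  For fits whose weights
#' are themselves estimated (IPTW/ATT), Wald intervals ignore the weight
#' estimation step; use [bootstrap_ci()] for those.
#'
#' Unobserved intermediate outcome categories are collapsed (with a
#' warning) before fitting, since their thresholds are not identified.
#'
#' @param data A data frame.
#' @param outcome Name of the ordinal outcome column (integer codes or
#'   ordered factor).
#' @param terms Character vector of model terms (column names, possibly
#'   with interactions such as `"gender:conspiracy"`); `NULL` fits the
#'   intercept-only model.
#' @param weights Optional positive observation weights (default 1).
#' @param start Optional warm start: a previous `clm_fit` on the same
#'   model (or a list with `thresholds` and `slopes`), e.g. the
#'   full-data fit when refitting bootstrap replicates.
#' @param compute_vcov Compute the observed-information covariance
#'   (default `TRUE`)?  Skipping it speeds up fits whose standard
#'   errors are never used, e.g. bootstrap or Monte-Carlo replicates.
#' @param control List with `maxit` (default 300), `grad_tol`
#'   (default 1e-6, scaled by total weight), `step_tol` (default 1e-12).
#' @return An object of class `"clm_fit"`: a list with `thresholds`
#'   (strictly increasing, named `"1|2"`, ...), `slopes` (named),
#'   `covariance` (over `c(thresholds, slopes)`), `log_likelihood`,
#'   `converged`, `n_effective` (total weight), `n`, `trace`
#'   (log-likelihood at each accepted iterate), and bookkeeping fields.
#' @seealso [wald_ci()], [bootstrap_ci()]
#' @export
#' @examples
#' d <- simulate_dataset(simulation_design(1, 400, beta = 0.7, gamma = 1, seed = 9))
#' fit <- fit_clm(d, "y", c("x", "z"))
#' coef(fit)
fit_clm <- function(data, outcome, terms = NULL, weights = NULL,
                    start = NULL, compute_vcov = TRUE, control = list()) {
  ctrl <- modifyList(list(maxit = 300L, grad_tol = 1e-6, step_tol = 1e-12),
                     control)
  stopifnot(is.data.frame(data), outcome %in% names(data))
  yraw <- data[[outcome]]
  if (is.factor(yraw)) yraw <- as.integer(yraw)
  if (anyNA(yraw) || any(yraw != round(yraw)) || any(yraw < 1)) {
    stop("outcome must be positive integer category codes", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(yraw)) else as.numeric(weights)
  if (length(w) != length(yraw) || anyNA(w) || any(w <= 0)) {
    stop("`weights` must be positive and match the data length", call. = FALSE)
  }

  # collapse unobserved categories: thresholds between them are not identified
  lev <- sort(unique(yraw))
  if (length(lev) < 2L) stop("outcome has fewer than 2 observed categories", call. = FALSE)
  if (length(lev) < max(yraw)) {
    warning("unobserved outcome categories collapsed before fitting")
  }
  y <- match(yraw, lev)
  J <- length(lev)

  if (is.null(terms) || length(terms) == 0L) {
    X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  } else {
    mm <- model.matrix(reformulate(terms), data = data)
    X <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    if (nrow(X) != length(y)) stop("missing values in model terms", call. = FALSE)
    const <- apply(X, 2L, function(col) max(col) - min(col) == 0)
    if (any(const)) {
      warning("dropping constant model column(s): ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
  }
  p <- ncol(X)

  # starting values: a supplied warm start on the same model, otherwise
  # thresholds at the weighted empirical cumulative logits
  theta0 <- NULL
  if (!is.null(start) &&
      length(start$thresholds) == J - 1L && length(start$slopes) == p) {
    a0 <- unname(start$thresholds)
    theta0 <- c(a0[1L], if (J > 2L) log(pmax(diff(a0), 1e-6)),
                unname(start$slopes))
  }
  if (is.null(theta0)) {
    cw <- cumsum(vapply(seq_len(J), function(j) sum(w[y == j]), 0))[seq_len(J - 1L)]
    alpha0 <- qlogis(pmin(pmax(cw / sum(w), 1e-4), 1 - 1e-4))
    alpha0 <- cummax(alpha0 + seq_len(J - 1L) * 1e-8)  # guard exact ties
    theta0 <- c(alpha0[1L],
                if (J > 2L) log(pmax(diff(alpha0), 1e-6)),
                rep(0, p))
  }

  # optimize under mean-normalized weights so convergence (and hence the
  # returned estimates) is invariant to rescaling all weights
  wbar <- mean(w)
  lik <- .clm_likelihood(y, X, w / wbar, J)
  opt <- .bfgs_maximize(theta0, lik$fn, lik$gr,
                        maxit = ctrl$maxit,
                        grad_tol = ctrl$grad_tol * length(y),
                        step_tol = ctrl$step_tol)
  opt$value <- opt$value * wbar
  opt$trace <- opt$trace * wbar
  alpha <- .theta_to_alpha(opt$par, J)
  slopes <- if (p > 0L) setNames(opt$par[J:(J - 1L + p)], colnames(X)) else numeric(0)

  # observed information in the natural parameterization
  par_nat <- c(alpha, slopes)
  covariance <- matrix(NA_real_, length(par_nat), length(par_nat))
  cov_ok <- !compute_vcov
  if (compute_vcov) {
    nat <- .clm_likelihood_natural(y, X, w, J)
    hess <- try(optimHess(par_nat, fn = nat$fn, gr = nat$gr), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      vc <- try(solve((hess + t(hess)) / 2), silent = TRUE)
      if (!inherits(vc, "try-error") && all(is.finite(vc))) {
        covariance <- (vc + t(vc)) / 2
        cov_ok <- TRUE
      }
    }
  }
  nm <- c(paste(lev[-J], lev[-1L], sep = "|"), names(slopes))
  dimnames(covariance) <- list(nm, nm)

  structure(
    list(thresholds = setNames(alpha, nm[seq_len(J - 1L)]),
         slopes = slopes,
         covariance = covariance,
         log_likelihood = opt$value,
         converged = opt$converged && (p == 0L || cov_ok),
         n_effective = sum(w),
         n = length(y),
         n_categories = J,
         levels = lev,
         trace = opt$trace,
         iterations = opt$iterations),
    class = "clm_fit"
  )
}

# Weighted cumulative-logit log-likelihood in the unconstrained
# parameterization theta = (alpha_1, log diff alpha, beta).
# Returns fn/gr for the NEGATIVE log-likelihood (minimization).
.clm_likelihood <- function(y, X, w, J) {
  p <- ncol(X)
  fn <- function(theta) {
    alpha <- .theta_to_alpha(theta, J)
    b <- theta[J:(J - 1L + p)]
    eta <- if (p > 0L) drop(X %*% b) else rep(0, length(y))
    A <- c(alpha, Inf)[y] - eta
    B <- c(-Inf, alpha)[y] - eta
    pr <- pmax(plogis(A) - plogis(B), 1e-300)
    -sum(w * log(pr))
  }
  gr <- function(theta) {
    alpha <- .theta_to_alpha(theta, J)
    b <- theta[J:(J - 1L + p)]
    eta <- if (p > 0L) drop(X %*% b) else rep(0, length(y))
    A <- c(alpha, Inf)[y] - eta
    B <- c(-Inf, alpha)[y] - eta
    pr <- pmax(plogis(A) - plogis(B), 1e-300)
    fA <- dlogis(A)   # 0 at +/-Inf
    fB <- dlogis(B)
    # d loglik / d alpha_k = sum_i w [1{y=k} fA - 1{y=k+1} fB] / pr
    up <- w * fA / pr
    dn <- w * fB / pr
    g_alpha <- vapply(seq_len(J - 1L), function(k) {
      sum(up[y == k]) - sum(dn[y == k + 1L])
    }, 0)
    g_b <- if (p > 0L) -drop(crossprod(X, w * (fA - fB) / pr)) else numeric(0)
    # chain rule to (alpha_1, log increments)
    g_theta_alpha <- numeric(J - 1L)
    g_theta_alpha[1L] <- sum(g_alpha)
    if (J > 2L) {
      incr <- exp(theta[2:(J - 1L)])
      g_theta_alpha[2:(J - 1L)] <- incr * rev(cumsum(rev(g_alpha[-1L])))
    }
    -c(g_theta_alpha, g_b)
  }
  list(fn = fn, gr = gr)
}

# Same likelihood in the natural (alpha, beta) parameterization,
# used only for the observed information at the optimum.
.clm_likelihood_natural <- function(y, X, w, J) {
  p <- ncol(X)
  fn <- function(par) {
    alpha <- par[seq_len(J - 1L)]
    b <- par[J:(J - 1L + p)]
    eta <- if (p > 0L) drop(X %*% b) else rep(0, length(y))
    A <- c(alpha, Inf)[y] - eta
    B <- c(-Inf, alpha)[y] - eta
    pr <- pmax(plogis(A) - plogis(B), 1e-300)
    -sum(w * log(pr))
  }
  gr <- function(par) {
    alpha <- par[seq_len(J - 1L)]
    b <- par[J:(J - 1L + p)]
    eta <- if (p > 0L) drop(X %*% b) else rep(0, length(y))
    A <- c(alpha, Inf)[y] - eta
    B <- c(-Inf, alpha)[y] - eta
    pr <- pmax(plogis(A) - plogis(B), 1e-300)
    fA <- dlogis(A)
    fB <- dlogis(B)
    up <- w * fA / pr
    dn <- w * fB / pr
    g_alpha <- vapply(seq_len(J - 1L), function(k) {
      sum(up[y == k]) - sum(dn[y == k + 1L])
    }, 0)
    g_b <- if (p > 0L) -drop(crossprod(X, w * (fA - fB) / pr)) else numeric(0)
    -c(g_alpha, g_b)
  }
  list(fn = fn, gr = gr)
}

.theta_to_alpha <- function(theta, J) {
  if (J == 2L) theta[1L] else cumsum(c(theta[1L], exp(theta[2:(J - 1L)])))
}

# BFGS maximizer of -fn with Armijo backtracking; records the objective
# (as a log-likelihood, i.e. -fn) at every accepted iterate.
.bfgs_maximize <- function(theta, fn, gr, maxit, grad_tol, step_tol) {
  np <- length(theta)
  H <- diag(np)
  f <- fn(theta)
  g <- gr(theta)
  trace <- -f
  converged <- max(abs(g)) < grad_tol
  it <- 0L
  while (!converged && it < maxit) {
    it <- it + 1L
    d <- -drop(H %*% g)
    if (sum(d * g) >= 0) {          # not a descent direction: reset
      H <- diag(np)
      d <- -g
    }
    step <- 1
    f_new <- Inf
    repeat {
      theta_new <- theta + step * d
      f_new <- fn(theta_new)
      if (is.finite(f_new) && f_new <= f + 1e-4 * step * sum(g * d)) break
      step <- step / 2
      if (step < 1e-14) break
    }
    if (!is.finite(f_new) || f_new > f) break   # no admissible step
    g_new <- gr(theta_new)
    s <- theta_new - theta
    yv <- g_new - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {               # BFGS inverse-Hessian update
      rho <- 1 / sy
      Vy <- drop(H %*% yv)
      H <- H - rho * (outer(s, Vy) + outer(Vy, s)) +
        rho^2 * (sum(yv * Vy) + sy) * outer(s, s)
    }
    rel_change <- (f - f_new) / max(1, abs(f))
    theta <- theta_new; f <- f_new; g <- g_new
    trace <- c(trace, -f)
    if (max(abs(g)) < grad_tol || rel_change < step_tol) {
      converged <- max(abs(g)) < grad_tol * 10  # honest flag at stagnation
      break
    }
  }
  if (max(abs(g)) < grad_tol) converged <- TRUE
  list(par = theta, value = -f, gradient = -g, converged = converged,
       trace = trace, iterations = it)
}

#' @export
print.clm_fit <- function(x, ...) {
  cat(sprintf("Weighted cumulative logit fit (n = %d, total weight = %.1f)\n",
              x$n, x$n_effective))
  if (length(x$slopes)) {
    cat("Slopes (log odds, positive = higher categories):\n")
    print(round(x$slopes, 4))
  }
  cat("Thresholds:\n")
  print(round(x$thresholds, 4))
  cat(sprintf("log-likelihood: %.3f  (converged: %s, %d iterations)\n",
              x$log_likelihood, x$converged, x$iterations))
  invisible(x)
}

#' @export
coef.clm_fit <- function(object, ...) object$slopes

#' @export
vcov.clm_fit <- function(object, ...) object$covariance

#' @export
logLik.clm_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$thresholds) + length(object$slopes),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.clm_fit <- function(object, ...) object$n

#' Wald confidence interval for an odds ratio
#'
#' Returns `OR = exp(beta_hat)` with the interval
#' `exp(beta_hat +/- z * SE)`, the SE taken from the fit's observed
#' information.  Only valid for fits whose weights are fixed (for
#' estimated IPTW/ATT weights use [bootstrap_ci()]).
#'
#' @param fit A converged [fit_clm()] object.
#' @param term Name of the slope.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame: `term`, `or_point`, `ci_low`,
#'   `ci_high`, `ci_method`.
#' @export
wald_ci <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "clm_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; no Wald interval", call. = FALSE)
  if (!term %in% names(fit$slopes)) stop("unknown term: ", term, call. = FALSE)
  b <- fit$slopes[[term]]
  se <- sqrt(fit$covariance[term, term])
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(term = term,
             or_point = exp(b),
             ci_low = exp(b - z * se),
             ci_high = exp(b + z * se),
             ci_method = "wald",
             stringsAsFactors = FALSE)
}

#' Percentile bootstrap confidence interval for weight-dependent fits
#'
#' Resamples rows with replacement (sampling weights travel with their
#' rows; resampling itself is uniform), re-runs the full estimation
#' recipe — typically propensity fitting, weight construction and the
#' weighted cumulative logit — on each replicate, and reports the
#' percentile interval of the odds ratio.  Failed replicates are dropped
#' and counted; more than 10% failures is an error.
#'
#' @param data The analysis table.
#' @param estimator Function `data -> named numeric` returning the
#'   log odds ratio(s) of interest (a scalar is treated as one unnamed
#'   term `"x"`).
#' @param n_boot Number of bootstrap replications (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return A data frame with one row per term: `term`, `or_point`
#'   (estimate on the original data), `ci_low`, `ci_high`,
#'   `ci_method = "bootstrap"`; the number of dropped replicates is in
#'   `attr(, "n_failures")`.
#' @export
bootstrap_ci <- function(data, estimator, n_boot = 500L, level = 0.95,
                         seed = NULL) {
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  stopifnot(is.function(estimator), is.data.frame(data))
  full <- estimator(data)
  if (is.null(names(full))) names(full) <- rep("x", length(full))

  old <- .save_rng()
  on.exit(.restore_rng(old))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot, length(full))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- try(estimator(data[idx, , drop = FALSE]), silent = TRUE)
    if (!inherits(est, "try-error") && all(is.finite(est))) {
      draws[b, ] <- est
    }
  }
  ok <- complete.cases(draws)
  if (mean(!ok) > 0.10) {
    stop(sprintf("bootstrap failed in %d/%d replicates (> 10%%)",
                 sum(!ok), n_boot), call. = FALSE)
  }
  a <- (1 - level) / 2
  out <- data.frame(
    term = names(full),
    or_point = exp(unname(full)),
    ci_low = exp(apply(draws[ok, , drop = FALSE], 2L, quantile, probs = a)),
    ci_high = exp(apply(draws[ok, , drop = FALSE], 2L, quantile, probs = 1 - a)),
    ci_method = "bootstrap",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_failures") <- sum(!ok)
  out
}

#' Collapse a 7-point Likert outcome to 5 categories
#'
#' Maps `{1,2,3} -> 1`, `4 -> 2`, `5 -> 3`, `6 -> 4`, `7 -> 5`,
#' collapsing the sparse bottom of the scale into its third category to
#' avoid numerically unstable thresholds.  Order preserving.
#'
#' @param y7 Integer vector with values in 1..7.
#' @return Integer vector with values in 1..5.
#' @export
recode_outcome <- function(y7) {
  if (anyNA(y7) || any(y7 != round(y7)) || any(y7 < 1 | y7 > 7)) {
    stop("`y7` must contain integers in 1..7", call. = FALSE)
  }
  c(1L, 1L, 1L, 2L, 3L, 4L, 5L)[as.integer(y7)]
}
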