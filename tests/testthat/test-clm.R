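test_that("unit weights reproduce the unweighted fit", {
  d <- simulate_dataset(simulation_design(1, 500, beta = 0.5, gamma = 1, seed = 2))
  f0 <- fit_clm(d, "y", c("x", "z"))
  f1 <- fit_clm(d, "y", c("x", "z"), weights = rep(1, nrow(d)))
  expect_equal(f1$slopes, f0$slopes, tolerance = 1e-6)
  expect_equal(f1$thresholds, f0$thresholds, tolerance = 1e-6)
})

test_that("intercept-only MLE equals the empirical cumulative logits", {
  counts <- c(15, 20, 30, 20, 15) * 2
  d <- data.frame(y = rep(1:5, counts))
  fit <- fit_clm(d, "y")
  expect_equal(unname(fit$thresholds),
               derive_intercepts(counts / sum(counts)), tolerance = 1e-6)
})

test_that("optimum matches a brute-force grid search on tiny data", {
  d <- tiny_ordinal()
  fit <- fit_clm(d, "y", "x")
  oracle <- grid_search_clm3(d$y, d$x)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-3)
  expect_gte(fit$log_likelihood, oracle$loglik - 1e-3)
  # weighted variant against the same oracle
  w <- rep(c(1, 2), 6)
  fitw <- fit_clm(d, "y", "x", weights = w)
  oraclew <- grid_search_clm3(d$y, d$x, w)
  expect_equal(fitw$log_likelihood, oraclew$loglik, tolerance = 1e-3)
})

test_that("estimates and standard errors agree with MASS::polr", {
  skip_if_not_installed("MASS")
  d <- simulate_dataset(simulation_design(1, 2000, beta = 0.5, gamma = 1, seed = 42))
  fit <- fit_clm(d, "y", c("x", "z"))
  pol <- MASS::polr(factor(y, ordered = TRUE) ~ x + z, data = d, Hess = TRUE)
  expect_equal(unname(fit$slopes), unname(coef(pol)), tolerance = 1e-4)
  expect_equal(unname(fit$thresholds), unname(pol$zeta), tolerance = 1e-4)
  expect_equal(sqrt(diag(fit$covariance))[["x"]],
               sqrt(diag(vcov(pol)))[["x"]], tolerance = 1e-3)
  # weighted agreement too
  set.seed(1); w <- runif(nrow(d), 0.5, 2)
  fitw <- fit_clm(d, "y", c("x", "z"), weights = w)
  polw <- suppressWarnings(
    MASS::polr(factor(y, ordered = TRUE) ~ x + z, data = d, weights = w))
  expect_equal(unname(fitw$slopes), unname(coef(polw)), tolerance = 1e-4)
})

test_that("log-likelihood is monotone over accepted iterations", {
  for (seed in c(4, 9, 23)) {
    d <- simulate_dataset(simulation_design(2, 800, beta = 1, gamma = 2, seed = seed))
    fit <- fit_clm(d, "y", c("x", "z"))
    expect_true(fit$converged)
    expect_true(all(diff(fit$trace) >= -1e-10))
  }
})

test_that("rescaling weights leaves point estimates unchanged", {
  d <- simulate_dataset(simulation_design(1, 600, beta = 0.5, gamma = 1, seed = 8))
  set.seed(2); w <- runif(nrow(d), 0.2, 3)
  f1 <- fit_clm(d, "y", c("x", "z"), weights = w)
  f5 <- fit_clm(d, "y", c("x", "z"), weights = 5 * w)
  expect_equal(f5$slopes, f1$slopes, tolerance = 1e-6)
  expect_equal(f5$thresholds, f1$thresholds, tolerance = 1e-6)
})

test_that("thresholds are strictly increasing and covariance symmetric PSD", {
  d <- simulate_dataset(simulation_design(1, 1000, beta = 0.25, gamma = 2, seed = 13))
  fit <- fit_clm(d, "y", c("x", "z"))
  expect_true(!is.unsorted(fit$thresholds, strictly = TRUE))
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-10)
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("unobserved intermediate categories are collapsed with a warning", {
  d <- data.frame(y = c(1L, 1L, 3L, 3L, 3L, 5L, 5L, 1L, 3L, 5L),
                  x = rep(0:1, 5))
  expect_warning(fit <- fit_clm(d, "y", "x"), "collapsed")
  expect_length(fit$thresholds, 2)  # 3 observed categories
})

test_that("degenerate inputs are rejected", {
  d <- tiny_ordinal()
  expect_error(fit_clm(d, "y", "x", weights = rep(-1, 12)), "positive")
  expect_error(fit_clm(data.frame(y = rep(1L, 5), x = 0:4 %% 2), "y", "x"),
               "fewer than 2")
  expect_warning(fit_clm(cbind(d, cc = 1), "y", c("x", "cc")), "constant")
})

test_that("Wald intervals follow the printed arithmetic", {
  fake <- structure(list(slopes = c(x = 0.5),
                         thresholds = c(`1|2` = -1),
                         covariance = matrix(0.01, 1, 1,
                                             dimnames = list("x", "x")),
                         converged = TRUE),
                    class = "clm_fit")
  ci <- wald_ci(fake, "x")
  expect_equal(ci$or_point, exp(0.5))
  expect_equal(ci$ci_low, exp(0.304), tolerance = 1e-3)
  expect_equal(ci$ci_high, exp(0.696), tolerance = 1e-3)
  # degenerate SE -> point interval; zero slope -> OR 1, symmetric on log scale
  fake$covariance[] <- 0
  ci0 <- wald_ci(fake, "x")
  expect_equal(ci0$ci_low, ci0$ci_high)
  fake$slopes[] <- 0; fake$covariance[] <- 0.04
  cis <- wald_ci(fake, "x")
  expect_equal(cis$or_point, 1)
  expect_equal(log(cis$ci_high), -log(cis$ci_low), tolerance = 1e-12)
  # or_point is exactly exp(slope)
  d <- simulate_dataset(simulation_design(1, 400, beta = 1, gamma = 1, seed = 6))
  fit <- fit_clm(d, "y", "x")
  expect_identical(wald_ci(fit, "x")$or_point, exp(fit$slopes[["x"]]))
  fake$converged <- FALSE
  expect_error(wald_ci(fake, "x"), "converge")
  expect_error(wald_ci(fit, "nope"), "unknown term")
})

test_that("bootstrap intervals validate input and handle degenerate recipes", {
  d <- tiny_ordinal()
  expect_error(bootstrap_ci(d, function(x) 0, n_boot = 0), ">= 1")
  # estimator blind to the data -> zero-width interval
  ci <- bootstrap_ci(d, function(x) c(x = 0.3), n_boot = 25, seed = 1)
  expect_equal(ci$ci_low, ci$ci_high)
  expect_equal(ci$or_point, exp(0.3))
  # too many replicate failures -> error (the first, full-data call succeeds)
  calls <- 0
  flaky <- function(x) {
    calls <<- calls + 1
    if (calls > 1 && calls %% 2 == 0) stop("boom")
    c(x = 0)
  }
  expect_error(bootstrap_ci(d, flaky, n_boot = 40, seed = 5), "10%")
})

test_that("bootstrap percentile interval brackets a stable estimate", {
  d <- simulate_dataset(simulation_design(1, 800, beta = 1, gamma = 0, seed = 31))
  est <- function(dd) {
    f <- fit_clm(dd, "y", "x", compute_vcov = FALSE)
    c(x = f$slopes[["x"]])
  }
  ci <- bootstrap_ci(d, est, n_boot = 60, seed = 7)
  expect_lt(ci$ci_low, ci$or_point)
  expect_gt(ci$ci_high, ci$or_point)
  expect_equal(attr(ci, "n_failures"), 0)
})

test_that("7-to-5 outcome recoding collapses the sparse bottom and preserves order", {
  expect_equal(recode_outcome(1:7), c(1L, 1L, 1L, 2L, 3L, 4L, 5L))
  set.seed(5)
  a <- sample(1:7, 60, TRUE); b <- pmin(a + sample(0:3, 60, TRUE), 7L)
  expect_true(all(recode_outcome(a) <= recode_outcome(b)))
  expect_error(recode_outcome(c(3, 8)), "1..7")
  expect_error(recode_outcome(c(0, 3)), "1..7")
})
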