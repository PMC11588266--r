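test_that("stabilized weights follow the printed formula", {
  # pi_hat equal to the treated proportion -> all weights 1
  x <- rep(c(1, 0), c(3, 3))
  expect_equal(stabilized_weights(rep(0.5, 6), x), rep(1, 6))
  # p_x = 0.5, pi = 0.25, treated -> 0.5 / 0.25 = 2
  x2 <- c(1, 0)
  w2 <- stabilized_weights(c(0.25, 0.25), x2)
  expect_equal(w2[1], 2)
  expect_equal(w2[2], (1 - 0.5) / (1 - 0.25))
  expect_error(stabilized_weights(c(0, 0.5), c(1, 0)), "clip")
  expect_equal(stabilized_weights(c(1e-9, 0.5), c(1, 0), clip = c(0.01, 0.99))[1],
               0.5 / 0.01)
})

test_that("ATT weights give treated 1 and controls their propensity odds", {
  expect_equal(att_weights(runif(5, 0.2, 0.8), rep(1, 5)), rep(1, 5))
  expect_equal(att_weights(c(0.5, 0.8), c(0, 0)), c(1, 4))
  expect_error(att_weights(c(1, 0.3), c(0, 0)), "clip")
})

test_that("stabilized weights average to about 1 per group when pi is correct", {
  d <- simulate_dataset(simulation_design(1, 5000, beta = 0.5, gamma = 1, seed = 17))
  ws <- stabilized_weights(d$z, d$x)  # oracle pi = z
  expect_equal(as.vector(tapply(ws, d$x, mean)), c(1, 1), tolerance = 0.05)
})

test_that("oracle ATT weighting matches the treated covariate distribution", {
  d <- simulate_dataset(simulation_design(1, 5000, beta = 0.5, gamma = 1, seed = 19))
  wa <- att_weights(d$z, d$x)
  treated_mean <- mean(d$z[d$x == 1])
  ctrl_weighted <- sum((wa * d$z)[d$x == 0]) / sum(wa[d$x == 0])
  expect_equal(ctrl_weighted, treated_mean, tolerance = 0.05)
})

test_that("SMD identities hold", {
  x <- rep(0:1, each = 100)
  v <- rep(c(-1, 1), 100)           # identical distribution in both groups
  expect_equal(smd(v, x), 0)
  v2 <- c(rep(c(-1, 1), 50), rep(c(0, 2), 50))  # means 0 vs 1, variances 1
  expect_equal(as.numeric(smd(v2, x)), 1)
  # zero variance: equal means -> 0, unequal -> error
  expect_equal(smd(rep(2, 200), x), 0)
  expect_error(smd(rep(c(1, 2), each = 100), x), "zero pooled variance")
  expect_error(smd(v, rep(1, 200)), "non-empty")
  # categorical: max over level indicators, levels attached
  f <- factor(rep(c("a", "b", "a", "a"), 50))
  s <- smd(f, x)
  expect_equal(as.numeric(s), max(attr(s, "levels")))
})

test_that("weighting by the true assignment probability balances the confounder", {
  d <- simulate_dataset(simulation_design(1, 5000, beta = 0.5, gamma = 2, seed = 23))
  before <- as.numeric(smd(d$z, d$x))
  after <- as.numeric(smd(d$z, d$x, stabilized_weights(d$z, d$x)))
  expect_gt(before, 0.3)
  expect_lt(after, 0.1)
})

test_that("Kish effective sample size identities hold", {
  expect_equal(effective_sample_size(rep(2.5, 40)), 40)
  expect_equal(effective_sample_size(c(1, 1, 1, 3)), 3)
  expect_error(effective_sample_size(numeric(0)), "empty")
  expect_error(effective_sample_size(c(1, -1)))
  set.seed(31)
  for (i in 1:10) {
    w <- rlnorm(50, sdlog = runif(1, 0.1, 1.5))
    ess <- effective_sample_size(w)
    expect_gt(ess, 0)
    expect_lte(ess, 50 + 1e-9)
  }
})

test_that("boosted propensities track the true assignment mechanism", {
  cfg <- propensity_config(n_trees = 200, learning_rate = 0.1)
  # no signal: fitted probabilities hover at the treated fraction
  set.seed(3)
  d0 <- data.frame(x = rbinom(3000, 1, 0.4), z = runif(3000))
  pi0 <- fit_propensity(d0, "z", cfg)
  expect_equal(mean(pi0), mean(d0$x), tolerance = 0.02)
  expect_lt(sd(pi0), 0.1)

  # scenario 1: binned means of pi_hat track z with calibration slope ~ 1
  d1 <- simulate_dataset(simulation_design(1, 5000, beta = 0.5, gamma = 1, seed = 5))
  pi1 <- fit_propensity(d1, "z", cfg)
  bins <- cut(d1$z, seq(0, 1, 0.1))
  binned <- tapply(pi1, bins, mean)
  truth <- tapply(d1$z, bins, mean)
  expect_lt(max(abs(binned - truth)), 0.08)
  expect_equal(unname(coef(lm(binned ~ truth))[2]), 1, tolerance = 0.15)

  # scenario 2: binned means track z^2
  d2 <- simulate_dataset(simulation_design(2, 5000, beta = 0.5, gamma = 1, seed = 6))
  pi2 <- fit_propensity(d2, "z", cfg)
  binned2 <- tapply(pi2, cut(d2$z, seq(0, 1, 0.1)), mean)
  truth2 <- tapply(d2$z^2, cut(d2$z, seq(0, 1, 0.1)), mean)
  expect_lt(max(abs(binned2 - truth2)), 0.08)
})

test_that("propensity fitting validates its inputs", {
  d <- data.frame(x = rep(1L, 20), z = runif(20))
  expect_error(fit_propensity(d, "z"), "single class")
  d2 <- data.frame(x = rep(0:1, 10), z = runif(20), cc = 1)
  expect_warning(fit_propensity(d2, c("z", "cc"),
                                propensity_config(n_trees = 5)), "constant")
  expect_error(propensity_config(n_trees = 0), ">= 1")
  expect_error(propensity_config(learning_rate = 0), "\\(0, 1\\]")
  expect_error(propensity_config(clip = c(0, 0.9)), "inside")
})

test_that("love-plot tables order covariates by unweighted imbalance", {
  before <- data.frame(covariate = c("a", "b"), smd = c(0.05, 0.5))
  after <- data.frame(covariate = c("a", "b"), smd = c(0.02, 0.07))
  tab <- love_plot_table(before, after, ess_before = 100, ess_after = 60)
  expect_equal(tab$covariate, c("b", "b", "a", "a"))
  expect_equal(tab$phase, rep(c("unweighted", "weighted"), 2))
  expect_equal(tab$smd, c(0.5, 0.07, 0.05, 0.02))
  expect_equal(attr(tab, "ess_after"), 60)
  expect_error(love_plot_table(before, data.frame(covariate = "c", smd = 1)),
               "differ")
  empty <- data.frame(covariate = character(0), smd = numeric(0))
  expect_equal(nrow(love_plot_table(empty, empty)), 0)
})

test_that("estimate_propensity bundles weights, balance and ESS coherently", {
  d <- simulate_dataset(simulation_design(1, 2000, beta = 0.5, gamma = 1, seed = 29))
  res <- estimate_propensity(d, "z", propensity_config(n_trees = 100))
  expect_true(all(res$weights > 0))
  expect_equal(res$p_x, mean(d$x))
  expect_lt(res$smd_table$smd_after, res$smd_table$smd_before)
  expect_lte(res$ess_by_group["treated"], sum(d$x == 1))
  # ATT: treated weights exactly 1
  resatt <- estimate_propensity(d, "z",
                                propensity_config(n_trees = 100, estimand = "ATT"))
  expect_true(all(resatt$weights[d$x == 1] == 1))
})
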