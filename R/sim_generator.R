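#' Describe one cell of the simulation grid
#'
#' A `simulation_design` bundles everything needed to draw confounded
#' ordinal datasets from one of the two generative scenarios:
#'
#' * **scenario 1** (correctly specified): treatment assignment
#'   `X ~ Bernoulli(Z)` and outcome linear predictor `beta*X + gamma*Z`;
#' * **scenario 2** (misspecified for linear adjustment):
#'   `X ~ Bernoulli(Z^2)` and linear predictor `beta*X + gamma*Z^2`.
#'
#' The confounder `Z` is uniform on (0, 1), so the marginal treatment
#' prevalence is 1/2 under scenario 1 and 1/3 under scenario 2.  The
#' ordinal outcome has `n_categories` levels drawn from a cumulative
#' logit model whose thresholds reproduce `baseline_probs` at zero
#' linear predictor (see [derive_intercepts()]).
#'
#' @param scenario 1 or 2.
#' @param n Sample size (positive integer).
#' @param beta Treatment-to-outcome log odds ratio.
#' @param gamma Confounder-to-outcome strength.
#' @param n_categories Number of outcome categories `J` (>= 2).
#' @param baseline_probs Length-`J` probability vector giving the
#'   category distribution at zero linear predictor.  The default is the
#'   symmetric 0.15/0.20/0.30/0.20/0.15.
#' @param seed Integer root seed for this design.
#' @return An object of class `"simulation_design"`.
#' @seealso [simulate_dataset()], [run_grid()]
#' @export
#' @examples
#' simulation_design(1, n = 500, beta = 0.5, gamma = 1, seed = 42)
simulation_design <- function(scenario, n, beta, gamma,
                              n_categories = 5L,
                              baseline_probs = c(0.15, 0.20, 0.30, 0.20, 0.15),
                              seed = 1L) {
  scenario <- as.integer(scenario)
  if (!scenario %in% c(1L, 2L)) {
    stop("`scenario` must be 1 or 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L) {
    stop("`n_categories` must be an integer >= 2", call. = FALSE)
  }
  .check_prob_vector(baseline_probs)
  if (length(baseline_probs) != n_categories) {
    stop("`baseline_probs` must have length `n_categories`", call. = FALSE)
  }
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  structure(
    list(scenario = scenario, n = n, beta = beta, gamma = gamma,
         n_categories = n_categories, baseline_probs = baseline_probs,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: scenario %d, n = %d, beta = %g, gamma = %g, J = %d, seed = %d\n",
    x$scenario, x$n, x$beta, x$gamma, x$n_categories, x$seed))
  invisible(x)
}

.check_prob_vector <- function(p) {
  if (!is.numeric(p) || length(p) < 2L || anyNA(p) || any(p <= 0)) {
    stop("baseline probabilities must be positive numbers", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("baseline probabilities must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Cumulative-logit thresholds from baseline category probabilities
#'
#' Returns the `J - 1` thresholds `alpha_j = logit(p_1 + ... + p_j)` of
#' a cumulative logit model whose category distribution at zero linear
#' predictor equals `baseline_probs`.  Thresholds are strictly
#' increasing by construction.
#'
#' @param baseline_probs Positive probability vector summing to 1.
#' @return Numeric vector of length `length(baseline_probs) - 1`.
#' @export
#' @examples
#' derive_intercepts(c(0.15, 0.20, 0.30, 0.20, 0.15))
derive_intercepts <- function(baseline_probs) {
  .check_prob_vector(baseline_probs)
  J <- length(baseline_probs)
  qlogis(cumsum(baseline_probs)[seq_len(J - 1L)])
}

#' Category probabilities of the cumulative logit model
#'
#' Computes `P(Y = j)` for each unit under the minus sign convention
#' `logit P(Y <= j) = alpha_j - eta`, where `eta` is the per-unit linear
#' predictor.  A positive `eta` therefore shifts mass to higher
#' categories.
#'
#' @param intercepts Strictly increasing threshold vector (length J-1).
#' @param eta Numeric vector of linear predictors (recycled if scalar).
#' @return An `length(eta) x J` matrix of category probabilities; rows
#'   sum to 1.
#' @export
#' @examples
#' category_probs(derive_intercepts(c(.15, .2, .3, .2, .15)), eta = 0)
category_probs <- function(intercepts, eta = 0) {
  if (is.unsorted(intercepts, strictly = TRUE)) {
    stop("`intercepts` must be strictly increasing", call. = FALSE)
  }
  cum <- plogis(outer(-eta, intercepts, `+`))  # P(Y <= j) = plogis(alpha_j - eta)
  cum <- cbind(cum, 1)
  probs <- cum - cbind(0, cum[, -ncol(cum), drop = FALSE])
  dimnames(probs) <- NULL
  probs
}

#' Confounded treatment assignment
#'
#' Draws `X_i ~ Bernoulli(tau_i)` with `tau_i = z_i` (scenario 1) or
#' `tau_i = z_i^2` (scenario 2), so that units with a larger confounder
#' value are more likely to be treated.
#'
#' @param z Confounder values in \[0, 1\].
#' @param scenario 1 or 2.
#' @return Integer 0/1 vector of the same length as `z`.
#' @export
assign_treatment <- function(z, scenario = 1) {
  if (!is.numeric(z) || anyNA(z) || any(z < 0 | z > 1)) {
    stop("`z` must be numeric in [0, 1]", call. = FALSE)
  }
  scenario <- as.integer(scenario)
  if (!scenario %in% c(1L, 2L)) stop("`scenario` must be 1 or 2", call. = FALSE)
  tau <- if (scenario == 1L) z else z^2
  rbinom(length(z), 1L, tau)
}

# Deterministic sub-stream seed derivation (kept below 2^31; the double
# product stays far below 2^53, so the arithmetic is exact).
.substream_seed <- function(root, k) {
  as.integer((as.double(root) * 69621 + 110351 * as.double(k)) %% 2147483647)
}

#' Simulate a confounded ordinal dataset
#'
#' Draws `Z ~ U(0,1)`, treatment via [assign_treatment()], and the
#' ordinal outcome from the cumulative logit model with linear predictor
#' `beta*X + gamma*Z` (scenario 1) or `beta*X + gamma*Z^2` (scenario 2),
#' under the minus sign convention (positive `beta` pushes treated units
#' toward higher categories).  Category sampling uses a single uniform
#' per unit inverted through the cumulative probabilities.
#'
#' Reproducibility: the design's root seed spawns separate sub-streams
#' for Z, X and Y, so the same design always yields the same data.  No
#' prefix-stability across different `n` is guaranteed.
#'
#' @param design A [simulation_design()].
#' @return A `data.frame` of class `"ordinal_dataset"` with columns
#'   `y` (integer 1..J), `x` (integer 0/1), `z` (numeric), and
#'   `sampling_weight` (all 1 for simulated data).
#' @export
#' @examples
#' d <- simulate_dataset(simulation_design(1, 200, beta = 0.5, gamma = 1, seed = 3))
#' table(d$y, d$x)
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  old <- .save_rng()
  on.exit(.restore_rng(old))

  set.seed(.substream_seed(design$seed, 1L))
  z <- runif(design$n)
  set.seed(.substream_seed(design$seed, 2L))
  x <- assign_treatment(z, design$scenario)
  zc <- if (design$scenario == 1L) z else z^2
  eta <- design$beta * x + design$gamma * zc
  probs <- category_probs(derive_intercepts(design$baseline_probs), eta)
  set.seed(.substream_seed(design$seed, 3L))
  y <- .sample_categories(probs)

  out <- data.frame(y = y, x = x, z = z, sampling_weight = 1)
  attr(out, "design") <- design
  class(out) <- c("ordinal_dataset", "data.frame")
  out
}

# Inverse-CDF draw of one category per row of a probability matrix.
.sample_categories <- function(probs) {
  J <- ncol(probs)
  upper <- upper.tri(diag(J), diag = TRUE) * 1   # row-wise cumulative sums
  cum <- probs %*% upper
  u <- runif(nrow(probs))
  as.integer(rowSums(u > cum[, -J, drop = FALSE]) + 1L)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Validate an ordinal dataset table
#'
#' Checks the column contract shared by the simulator and the fitters:
#' `y` integer-valued in `1..J`, `x` binary 0/1, `z` numeric, optional
#' positive `sampling_weight` (defaulted to 1).
#'
#' @param data A data frame with columns `y`, `x`, `z` and optionally
#'   `sampling_weight`.
#' @param n_categories Number of outcome categories `J`.
#' @return The validated data frame with class `"ordinal_dataset"`.
#' @export
as_ordinal_dataset <- function(data, n_categories = max(data$y)) {
  stopifnot(is.data.frame(data), all(c("y", "x", "z") %in% names(data)))
  y <- data$y
  if (anyNA(y) || any(y != as.integer(y)) || any(y < 1L | y > n_categories)) {
    stop("`y` must be integers in 1..J", call. = FALSE)
  }
  if (anyNA(data$x) || !all(data$x %in% c(0, 1))) {
    stop("`x` must be 0/1", call. = FALSE)
  }
  if (is.null(data$sampling_weight)) data$sampling_weight <- 1
  if (any(data$sampling_weight <= 0)) {
    stop("`sampling_weight` must be positive", call. = FALSE)
  }
  data$y <- as.integer(y)
  data$x <- as.integer(data$x)
  class(data) <- unique(c("ordinal_dataset", class(data)))
  data
}

#' Read and write ordinal datasets as CSV
#'
#' Plain CSV with columns `y, x, z, sampling_weight`.
#'
#' @param data An ordinal dataset (see [as_ordinal_dataset()]).
#' @param path File path.
#' @return `write_ordinal_dataset()` returns `path` invisibly;
#'   `read_ordinal_dataset()` returns the validated dataset.
#' @export
write_ordinal_dataset <- function(data, path) {
  data <- as_ordinal_dataset(as.data.frame(data))
  write.csv(data[c("y", "x", "z", "sampling_weight")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ordinal_dataset
#' @export
read_ordinal_dataset <- function(path) {
  as_ordinal_dataset(read.csv(path))
}

#' Load a simulation grid from a YAML or JSON config file
#'
#' The config lists `scenario`, `n`, `beta`, `gamma` (each scalar or
#' vector; the full cross product is taken), plus optional `K`, `seed`,
#' `n_categories` and `baseline_probs`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `designs` (list of
#'   [simulation_design()]), `K`, and `seed`.
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  for (key in c("scenario", "n", "beta", "gamma")) {
    if (is.null(cfg[[key]])) stop("config missing key: ", key, call. = FALSE)
  }
  K <- if (is.null(cfg$K)) 1000L else as.integer(cfg$K)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  J <- if (is.null(cfg$n_categories)) 5L else as.integer(cfg$n_categories)
  bp <- if (is.null(cfg$baseline_probs)) c(.15, .2, .3, .2, .15) else as.numeric(cfg$baseline_probs)
  grid <- expand.grid(scenario = cfg$scenario, n = cfg$n,
                      beta = cfg$beta, gamma = cfg$gamma,
                      KEEP.OUT.ATTRS = FALSE)
  designs <- lapply(seq_len(nrow(grid)), function(i) {
    simulation_design(grid$scenario[i], grid$n[i], grid$beta[i], grid$gamma[i],
                      n_categories = J, baseline_probs = bp, seed = seed)
  })
  list(designs = designs, K = K, seed = seed)
}
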