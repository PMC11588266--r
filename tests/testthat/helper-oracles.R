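# Shared fixtures and independent oracles for the test suite.

# A tiny fixed ordinal dataset (n = 12, J = 3, one binary covariate),
# small enough for brute-force likelihood search.
tiny_ordinal <- function() {
  data.frame(
    y = c(1L, 2L, 3L, 2L, 1L, 3L, 2L, 2L, 3L, 1L, 2L, 3L),
    x = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L)
  )
}

# Weighted cumulative-logit log-likelihood computed from first
# principles (independent of the package's fitter internals).
clm3_loglik <- function(a1, a2, b, y, x, w = rep(1, length(y))) {
  if (a2 <= a1) return(-Inf)
  eta <- b * x
  c1 <- plogis(a1 - eta)
  c2 <- plogis(a2 - eta)
  p <- cbind(c1, c2 - c1, 1 - c2)
  sum(w * log(p[cbind(seq_along(y), y)]))
}

# Brute-force maximum of the J = 3 likelihood by iteratively refined
# grid search over (a1, a2, b).
grid_search_clm3 <- function(y, x, w = rep(1, length(y)),
                             rounds = 4L, span = 4, npts = 21L) {
  center <- c(a1 = -1, a2 = 1, b = 0)
  best <- -Inf
  for (r in seq_len(rounds)) {
    g1 <- seq(center["a1"] - span, center["a1"] + span, length.out = npts)
    g2 <- seq(center["a2"] - span, center["a2"] + span, length.out = npts)
    gb <- seq(center["b"] - span, center["b"] + span, length.out = npts)
    for (a1 in g1) for (a2 in g2) for (b in gb) {
      ll <- clm3_loglik(a1, a2, b, y, x, w)
      if (ll > best) {
        best <- ll
        center <- c(a1 = a1, a2 = a2, b = b)
      }
    }
    span <- span / 5
  }
  list(par = center, loglik = best)
}

# Copy of a simulation design with a different seed.
within_seed <- function(design, seed) {
  design$seed <- as.integer(seed)
  design
}

# Random probability vector on the simplex.
random_simplex <- function(J) {
  p <- runif(J, 0.05, 1)
  p / sum(p)
}
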