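# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Natural cubic spline via the truncated-power representation (all knots,
# boundary included): N1 = 1, N2 = x, N_{k+2} = d_k - d_{K-1} with
# d_k(x) = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k).
tp_natural_basis <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  dk <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  out <- cbind(1, x)
  for (k in seq_len(K - 2L)) out <- cbind(out, dk(k) - dk(K - 1L))
  out
}

# Scalar DerSimonian-Laird random-effects pooling (textbook formulas).
dl_pool <- function(y, v) {
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_f)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w2 <- 1 / (v + tau2)
  list(mu = sum(w2 * y) / sum(w2), var = 1 / sum(w2), tau2 = tau2)
}

# Small daily series with known structure, for fitting tests.
toy_dates <- function(n, start = "2010-01-01") {
  seq(as.Date(start), by = "day", length.out = n)
}

# Compact simulation configuration for fast fitting tests: 3 analysis years,
# 60-day maximum lag.
small_config <- function(pattern = 1, concurvity = "low", n_years = 3,
                         lag_max = 60) {
  sim_config(n_years = n_years, burn_in_days = lag_max, concurvity = concurvity,
             pattern = pattern, lag_max = lag_max)
}
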