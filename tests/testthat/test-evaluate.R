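test_that("study summaries have the oracle limits", {
  truth <- 0.01
  # degenerate oracle estimator: always returns the truth with a positive SE
  est <- rep(truth, 40)
  se <- rep(0.002, 40)
  covered <- rep(TRUE, 40)
  s <- longlag:::summarize_estimates(est, se, covered, truth)
  expect_equal(s$bias_percent, 0)
  expect_equal(s$coverage_percent, 100)
  expect_equal(s$sd_estimates, 0)
  expect_equal(s$n_effective, 40L)
})

test_that("coverage computation is invariant to consistent unit rescaling", {
  set.seed(191)
  truth <- 0.01
  est <- rnorm(200, truth, 0.002)
  se <- rep(0.002, 200)
  covered <- abs(est - truth) <= 1.96 * se
  s1 <- longlag:::summarize_estimates(est, se, covered, truth)
  s2 <- longlag:::summarize_estimates(est * 10, se * 10, covered, truth * 10)
  expect_equal(s1$coverage_percent, s2$coverage_percent)
  expect_equal(s1$bias_percent, s2$bias_percent, tolerance = 1e-10)
})

test_that("a correctly specified method attains near-nominal coverage at small scale", {
  cfg <- small_config()
  res <- run_study(cfg,
                   methods = list(method_spec("alt", "4,2,2", lag = c(0, 60),
                                              lag_df = 5)),
                   n_reps = 60, seed = 300)
  expect_s3_class(res, "evaluation_result")
  # binomial band around 95% at 60 replicates
  expect_gte(res$coverage_percent, 85)
  expect_lte(res$coverage_percent, 100)
  expect_equal(res$truth, 0.01)
  expect_equal(res$n_effective, 60L)
})

test_that("lag curve summaries reduce to the truth for degenerate input", {
  pat <- make_lag_pattern(1, 60)
  curves <- rbind(pat$observable, pat$observable)
  s <- lag_curve_summary(curves, pat)
  expect_equal(s$rmse, rep(0, 61))
  expect_equal(s$mean, pat$observable, ignore_attr = TRUE)
  expect_true(all(s$lower <= s$mean + 1e-12 & s$mean <= s$upper + 1e-12))
  expect_error(lag_curve_summary(curves[, 1:10], pat), "length")
})

test_that("estimated mean lag curve tracks the generating pattern", {
  cfg <- small_config()
  res <- run_study(cfg,
                   methods = list(method_spec("alt", "4,2,2", lag = c(0, 60),
                                              lag_df = 5)),
                   n_reps = 40, seed = 400, keep_lag_curves = TRUE)
  curves <- attr(res, "lag_curves")$alt
  pat <- make_lag_pattern(1, 60)
  s <- lag_curve_summary(curves, pat)
  # pointwise: mean curve within 4 empirical SEs of the truth (generous
  # multiplier for 40 replicates across 61 correlated lags)
  expect_true(all(abs(s$mean - s$truth) < 4 * s$se + 1e-12))
})

test_that("orthogonalized long-lag adjustment leaves the short-lag estimate unchanged", {
  # linear-model analogue of the confounding experiment: when the long-lag
  # block is exactly orthogonal to the short-lag regressor and the intercept,
  # its inclusion cannot move the short-lag coefficient
  set.seed(201)
  n <- 800
  x <- rnorm(n)
  x01 <- as.numeric(stats::filter(x, c(1, 1), sides = 1)); x01[1] <- x[1]
  Z <- sapply(2:10, function(l) c(rep(0, l), x[1:(n - l)]))
  X0 <- cbind(1, x01)
  Zo <- Z - X0 %*% solve(crossprod(X0), crossprod(X0, Z))
  y <- x01 * 0.5 + rowSums(Z) * 0.1 + rnorm(n)
  b_without <- coef(lm(y ~ x01))["x01"]
  b_with <- coef(lm(y ~ x01 + Zo))["x01"]
  expect_lt(abs(b_with - b_without), 1e-8)
})

test_that("long-lag exposure confounds the short-lag estimate in the expected direction", {
  # the confounding pathway needs the full two-year displacement structure;
  # a running-time spline stands in for the conventional adjustment
  cfg <- sim_config(pattern = 2, concurvity = "low")
  res <- confounding_experiment(cfg, time_specs = list("t:10/yr"), n_reps = 12,
                                seed = 500, adjust_df = 5)
  expect_equal(nrow(res), 2L)
  unadj <- res$bias_percent[!res$adjusted]
  adj <- res$bias_percent[res$adjusted]
  # adjusting for lags 2..L shrinks the magnitude of the bias
  expect_lt(abs(adj), abs(unadj))
  expect_gt(abs(unadj), 15)  # the confounding is material when unadjusted
})

test_that("truncating the pattern to lags 0-1 removes the confounder", {
  cfg <- small_config(pattern = 1, lag_max = 60)
  # rebuild the config with a pattern that has no long-lag mass
  pat <- make_lag_pattern(1, 60)
  short <- pat$observable[1:2]
  idx_n <- 60 + round(3 * 365.25)
  est <- matrix(NA_real_, 30, 2)
  for (r in 1:30) {
    set.seed(600 + r)
    idx <- date_index(toy_dates(idx_n, "2002-01-01"))
    x <- generate_exposure(idx, concurvity = "low")
    b <- baseline_model(log(100), amp_annual = 0.12, peak_doy = 15)
    mu <- exp(log(100) + 0.12 * cos(2 * pi * (idx$doy - 15) / 365) +
                short[1] * x + short[2] * c(NA, x[-length(x)]))
    y <- suppressWarnings(rpois(idx_n, mu))
    dat <- data.frame(date = idx$date, exposure = x, outcome = y)
    dat$outcome[1:60] <- NA
    f0 <- suppressWarnings(dlm(dat, "4,2,2", lag = c(0, 1), lag_df = 1))
    f1 <- suppressWarnings(dlm(dat, "4,2,2", lag = c(0, 1), lag_df = 1,
                               adjust_lags = c(2, 60), adjust_df = 4))
    est[r, ] <- c(cumulative_effect(f0)$beta_bar, cumulative_effect(f1)$beta_bar)
  }
  truth <- sum(short)
  bias <- 100 * (colMeans(est) - truth) / truth
  # both near-unbiased: no long-lag mass exists to confound
  expect_lt(max(abs(bias)), 15)
})

test_that("scenario table assembles all scenario-method combinations", {
  res <- reproduce_table2(n_reps = 2, n_years = 2, seed = 1, lag_max = 60,
                          lag_df = 4)
  expect_equal(nrow(res), 16L)
  expect_setequal(unique(res$method),
                  c("unadjusted", "ncs_t_4yr", "ncs_t_10yr", "10,5,5"))
  expect_setequal(unique(paste(res$concurvity, res$pattern)),
                  c("low 1", "low 2", "high 1", "high 2"))
})
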