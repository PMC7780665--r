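test_that("lag patterns meet their cumulative and shape contracts", {
  p1 <- make_lag_pattern(1, 730)
  p2 <- make_lag_pattern(2, 730)
  expect_lt(abs(sum(p1$observable) - 0.01), 1e-12)
  expect_lt(abs(sum(p2$observable) - 0.001), 1e-12)
  # the strongest marginal effect is at the most proximal lag
  expect_equal(unname(which.max(p1$observable)), 1L)
  expect_equal(unname(which.max(p2$observable)), 1L)
  # component curves are non-negative
  expect_gte(min(p1$actual), 0); expect_gte(min(p1$displacement), 0)
  expect_gte(min(p2$actual), 0); expect_gte(min(p2$displacement), 0)
  # pattern 2's displacement spreads far and drives the observable negative
  # at intermediate lags; pattern 1's displacement is short-horizon
  expect_true(any(p2$observable[100:500] < 0))
  expect_false(any(p1$observable[100:500] < 0))
  expect_gt(sum(p1$displacement[1:121]) / sum(p1$displacement), 0.5)
  expect_lt(sum(p2$displacement[1:121]) / sum(p2$displacement), 0.25)
  expect_error(make_lag_pattern(3), "must be 1 or 2")
})

test_that("zero-displacement variant reduces to the non-negative actual curve", {
  p <- make_lag_pattern(1, 200, displacement = FALSE)
  expect_equal(p$observable, p$actual)
  expect_gte(min(p$observable), 0)
  expect_lt(abs(sum(p$observable) - 0.01), 1e-12)
})

test_that("cumulative sums are invariant to the target override", {
  p <- make_lag_pattern(1, 730, target = 0.0042)
  expect_lt(abs(sum(p$observable) - 0.0042), 1e-14)
})

test_that("exposure generator honours sigma, concurvity and the lognormal mean", {
  idx <- date_index(toy_dates(4000, "2002-01-01"))
  b0 <- baseline_model(log(50), amp_annual = 0.2, peak_doy = 60, sigma_log = 0)
  set.seed(141)
  x0 <- generate_exposure(idx, b0, "low")
  m <- log(50) + 0.2 * cos(2 * pi * (idx$doy - 60) / 365)
  expect_equal(log(x0), m, tolerance = 1e-12)
  b <- baseline_model(log(50), amp_annual = 0.2, peak_doy = 60, sigma_log = 0.4)
  set.seed(142); xl <- generate_exposure(idx, b, "low")
  set.seed(142); xh <- generate_exposure(idx, b, "high")
  r <- sd(log(xh) - m) / sd(log(xl) - m)
  expect_lt(abs(r - 0.1), 0.005)
  expect_lt(abs(mean(log(xl)) - mean(m)), 3 * 0.4 / sqrt(4000))
})

test_that("outcome counts follow the log-linear distributed-lag mean", {
  idx <- date_index(toy_dates(3000, "2002-01-01"))
  ob <- baseline_model(log(100), amp_annual = 0.1, peak_doy = 15)
  null_pat <- make_lag_pattern(1, 60, target = 1e-12)  # effectively zero effect
  set.seed(151)
  x <- rlnorm(3000, log(50), 0.3)
  y <- generate_outcome(idx, ob, null_pat, x)
  expect_true(all(is.na(y[1:60])))
  mu <- exp(log(100) + 0.1 * cos(2 * pi * (idx$doy - 15) / 365))[-(1:60)]
  expect_lt(abs(mean(y[-(1:60)]) - mean(mu)), 3 * sqrt(mean(mu) / 2940))
})

test_that("doubling the lag pattern raises every conditional mean", {
  idx <- date_index(toy_dates(400, "2002-01-01"))
  ob <- baseline_model(log(100))
  pat <- make_lag_pattern(1, 60)
  pat2 <- pat
  pat2$observable <- pat$observable * 2
  set.seed(161)
  x <- rlnorm(400, log(50), 0.3)
  mu1 <- exp(log(100) + drop(lag_matrix(x, 60) %*% pat$observable))
  mu2 <- exp(log(100) + drop(lag_matrix(x, 60) %*% pat2$observable))
  ok <- !is.na(mu1)
  expect_true(all(mu2[ok] > mu1[ok]))
})

test_that("simulated series are reproducible bit-for-bit and calibrated near the target rate", {
  cfg <- small_config()
  a <- simulate_series(cfg, seed = 171)
  b <- simulate_series(cfg, seed = 171)
  expect_identical(a, b)
  c2 <- simulate_series(cfg, seed = 172)
  expect_false(identical(a$exposure, c2$exposure))
  expect_lt(abs(mean(a$outcome, na.rm = TRUE) - 100) / 100, 0.15)
  expect_s3_class(a, "timeseries_table")
})

test_that("multi-city generator spreads heterogeneity with the requested SD", {
  set.seed(181)
  betas <- replicate(400, draw_city_effects(3, 0.01, 0.002))
  expect_lt(abs(sd(betas) - 0.002) / 0.002, 0.1)
  cfg <- small_config()
  cities0 <- generate_multicity(cfg, n_cities = 3, heterogeneity_sd = 0, seed = 5)
  b0 <- attr(cities0, "city_betas")
  expect_equal(b0, rep(0.01, 3))
  cities <- generate_multicity(cfg, n_cities = 3, heterogeneity_sd = 0.002, seed = 5)
  expect_length(cities, 3L)
  # disjoint streams: exposure series differ across cities
  expect_false(identical(cities[[1]]$exposure, cities[[2]]$exposure))
  # per-city truth attribute matches the drawn effect
  for (i in 1:3)
    expect_equal(attr(cities[[i]], "truth")$beta_bar,
                 attr(cities, "city_betas")[i], tolerance = 1e-10)
})
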