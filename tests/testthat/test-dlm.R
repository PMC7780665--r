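test_that("near-null fit recovers the closed-form Poisson MLE", {
  set.seed(71)
  n <- 2000
  y <- rpois(n, exp(2))
  dat <- data.frame(date = toy_dates(n), exposure = rnorm(n), outcome = y)
  fit <- dlm(dat, "", lag = c(0, 0), lag_df = 1)
  # exposure is centred noise unrelated to y, so the intercept estimates
  # log(E[Y]) = 2; closed-form MLE SE is sqrt(1/(n exp(2)))
  expect_equal(unname(fit$coefficients["(Intercept)"]), 2,
               tolerance = 3 * sqrt(1 / (n * exp(2))))
  # constant exposure is collinear with the intercept and must error
  dat$exposure <- rep(1, n)
  expect_error(dlm(dat, "", lag = c(0, 0), lag_df = 1), "collinear")
})

test_that("Pearson dispersion is near 1 for pure Poisson data", {
  set.seed(81)
  n <- 4000
  idx <- date_index(toy_dates(n))
  mu <- exp(log(80) + 0.1 * cos(2 * pi * idx$doy / 365))
  dat <- data.frame(date = idx$date, exposure = rnorm(n, 50, 5),
                    outcome = rpois(n, mu))
  fit <- dlm(dat, "doy:4", lag = c(0, 0), lag_df = 1)
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
  fit_pinned <- dlm(dat, "doy:4", lag = c(0, 0), lag_df = 1, dispersion = "fixed")
  expect_equal(fit_pinned$dispersion, 1)
})

test_that("unconstrained fit matches an independent glm() route exactly", {
  cfg <- small_config()
  dat <- simulate_series(cfg, seed = 91)
  fit <- dlm(dat, "4,2,2", lag = c(0, 10), lag_df = 11)   # identity transform
  ce <- cumulative_effect(fit)
  # oracle: stats::glm on the explicitly constructed lagged design
  M <- lag_matrix(dat$exposure, 10)
  used <- complete.cases(M) & is.finite(dat$outcome)
  # running time variables stay anchored at the table start, as in the model
  idxu <- date_index(dat$date)[used, ]
  B <- build_time_basis(idxu, time_basis_spec("4,2,2"))
  df <- data.frame(y = dat$outcome[used], M[used, ], B)
  g <- glm(y ~ ., data = df, family = quasipoisson(),
           control = glm.control(epsilon = 1e-12))
  lag_cols <- 2:12
  bb <- sum(coef(g)[lag_cols])
  se <- sqrt(sum(vcov(g)[lag_cols, lag_cols]))
  expect_lt(abs(ce$beta_bar - bb) / abs(bb), 1e-8)
  expect_lt(abs(ce$se - se) / se, 1e-6)
  expect_equal(fit$dispersion, summary(g)$dispersion, tolerance = 1e-8)
})

test_that("cumulative effect closed forms and unit-scaling invariance hold", {
  cfg <- small_config()
  dat <- simulate_series(cfg, seed = 101)
  fit <- dlm(dat, "4,2,2", lag = c(0, 60), lag_df = 4)
  ce <- cumulative_effect(fit)
  expect_equal(ce$percent_increase_per_10, 100 * (exp(10 * ce$beta_bar) - 1))
  expect_equal(sum(ce$lag_curve$estimate), ce$beta_bar, tolerance = 1e-10)
  # scaling exposure by 10 divides beta_bar by 10, leaves percent unchanged
  dat10 <- dat
  dat10$exposure <- dat10$exposure * 10
  ce10 <- cumulative_effect(dlm(dat10, "4,2,2", lag = c(0, 60), lag_df = 4))
  expect_equal(ce10$beta_bar * 10, ce$beta_bar, tolerance = 1e-6)
  # percent increase per 10 units of the rescaled exposure is unchanged
  expect_equal(100 * (exp(10 * 10 * ce10$beta_bar) - 1),
               ce$percent_increase_per_10, tolerance = 1e-6)
  # sub-window errors
  expect_error(cumulative_effect(fit, c(0, 100)), "lag_range")
})

test_that("delta-method SE of the cumulative matches Monte-Carlo propagation", {
  cfg <- small_config()
  dat <- simulate_series(cfg, seed = 111)
  fit <- dlm(dat, "4,2,2", lag = c(0, 60), lag_df = 4)
  ce <- cumulative_effect(fit)
  theta <- fit$coefficients[fit$theta_idx]
  vth <- fit$vcov[fit$theta_idx, fit$theta_idx]
  set.seed(112)
  ch <- chol(vth)
  draws <- matrix(rnorm(10000 * length(theta)), 10000) %*% ch
  draws <- sweep(draws, 2, theta, "+")
  cw <- colSums(fit$constraint$W)
  mc_sd <- sd(draws %*% cw)
  expect_lt(abs(mc_sd - ce$se) / ce$se, 0.02)
})

test_that("reduced coefficients are recovered within reported uncertainty", {
  cfg <- small_config(n_years = 3, lag_max = 60)
  hits <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    dat <- simulate_series(cfg, seed = 7000 + r)
    truth <- attr(dat, "truth")$beta_bar
    ce <- cumulative_effect(suppressWarnings(
      dlm(dat, "4,2,2", lag = c(0, 60), lag_df = 5)))
    hits <- hits + (abs(ce$beta_bar - truth) <= 3 * ce$se)
  }
  # 3-SE band: essentially all replicates should fall inside
  expect_gte(hits / n_rep, 0.99)
})

test_that("a short unconstrained fit isolates a lag-0-only effect", {
  set.seed(121)
  n <- 1200
  idx <- date_index(toy_dates(n))
  ok_cases <- 0L
  for (r in 1:50) {
    x <- rlnorm(n, log(50), 0.3)
    mu <- exp(log(60) + 0.002 * x)
    y <- rpois(n, mu)
    dat <- data.frame(date = idx$date, exposure = x, outcome = y)
    dat$outcome[1:7] <- NA
    fit <- dlm(dat, "", lag = c(0, 7), lag_df = 8)
    th <- fit$coefficients[fit$theta_idx]
    se <- sqrt(diag(fit$vcov)[fit$theta_idx])
    ok <- abs(th[1] - 0.002) <= 3 * se[1] && all(abs(th[-1]) <= 3 * se[-1])
    ok_cases <- ok_cases + ok
  }
  expect_gte(ok_cases / 50, 0.90)
})

test_that("fit fails informatively on degenerate inputs", {
  n <- 200
  dat <- data.frame(date = toy_dates(n), exposure = rnorm(n, 10),
                    outcome = rep(0L, n))
  expect_error(dlm(dat, "", lag = c(0, 0), lag_df = 1), "identically zero")
  dat$outcome <- rpois(n, 3) + 0.5
  expect_error(dlm(dat, "", lag = c(0, 0), lag_df = 1), "integer")
})

test_that("model methods expose coefficients, residuals and predictions coherently", {
  cfg <- small_config()
  dat <- simulate_series(cfg, seed = 131)
  fit <- dlm(dat, "4,2,2", lag = c(0, 60), lag_df = 4)
  expect_equal(length(coef(fit)), nrow(vcov(fit)))
  expect_equal(predict(fit, "response"), fitted(fit))
  expect_equal(residuals(fit, "response"), fit$y - fitted(fit))
  expect_equal(length(predict(fit)), fit$n_used)
  s <- summary(fit)
  expect_s3_class(s, "summary.dlm")
  expect_equal(unname(s$coefficients[, 1]), unname(coef(fit)))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n_used, 2L))
})
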