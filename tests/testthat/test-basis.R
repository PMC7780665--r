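test_that("natural spline basis is affine for df = 1 and full rank in general", {
  x <- 1:100
  B1 <- ns_basis(x, 1)
  expect_equal(ncol(B1), 1L)
  # affine in x: second differences vanish
  expect_lt(max(abs(diff(diff(B1[, 1])))), 1e-10)
  B4 <- ns_basis(x, 4)
  expect_equal(dim(B4), c(100L, 4L))
  expect_equal(qr(cbind(1, B4))$rank, 5L)
  expect_error(ns_basis(c(1, 2, 3), 3), "distinct")
})

test_that("spline function space matches the truncated-power natural-spline oracle", {
  x <- seq(0, 1, length.out = 200)
  y <- x^3
  B <- ns_basis(x, 8)
  all_knots <- c(attr(B, "boundary_knots")[1], attr(B, "knots"),
                 attr(B, "boundary_knots")[2])
  O <- tp_natural_basis(x, all_knots)
  rss <- function(M) sum(qr.resid(qr(M), y)^2)
  r1 <- rss(cbind(1, B)); r2 <- rss(O)
  expect_lt(abs(r1 - r2) / r2, 1e-8)
})

test_that("time basis blocks have the documented column counts", {
  idx <- date_index(seq(as.Date("2002-01-01"), as.Date("2013-12-31"), by = "day"))
  expect_equal(ncol(build_time_basis(idx, time_basis_spec("t:4/yr"))), 48L)
  B <- build_time_basis(idx, time_basis_spec("10,5,5"))
  expect_equal(ncol(B), 10L + 11L + 5L + 5L)
  expect_equal(ncol(build_time_basis(idx, time_basis_spec(""))), 0L)
  idx1 <- date_index(seq(as.Date("2002-01-01"), as.Date("2002-12-31"), by = "day"))
  expect_warning(B1 <- build_time_basis(idx1, time_basis_spec("doy:4+year")),
                 "single calendar year")
  expect_equal(ncol(B1), 4L)
})

test_that("spec grammar parses shorthand and rejects malformed components", {
  s <- time_basis_spec("10,5,5")
  kinds <- vapply(s$components, `[[`, character(1), "kind")
  expect_equal(kinds, c("ncs_doy", "year_indicator", "ncs_week", "ncs_month"))
  expect_error(time_basis_spec("doy:4+doy:5"), "more than once")
  expect_error(time_basis_spec("banana:3"), "cannot parse")
  expect_error(time_basis_spec("doy:0.5"), ">= 1")
})

test_that("day-of-year basis rows repeat identically across years", {
  idx <- date_index(seq(as.Date("2005-01-01"), as.Date("2007-12-31"), by = "day"))
  B <- build_time_basis(idx, time_basis_spec("doy:10"))
  for (doy in c(1, 100, 200, 365)) {
    rows <- B[idx$doy == doy, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(c) diff(range(c)))), 0)
  }
})

test_that("residual variance diagnostic has the closed-form limits", {
  idx <- date_index(toy_dates(500))
  set.seed(11)
  y <- rnorm(500)
  d0 <- residual_variance_diagnostic(y, time_basis_spec(""), idx)
  expect_equal(d0$residual_variance, var(y))
  expect_equal(d0$r_squared, 0)
  B <- build_time_basis(idx, time_basis_spec("t:3"))
  d1 <- residual_variance_diagnostic(B[, 2], time_basis_spec("t:3"), idx)
  expect_equal(d1$r_squared, 100, tolerance = 1e-10)
  expect_lt(d1$residual_variance, 1e-20)
})

test_that("R squared is monotone over nested bases and variance never increases", {
  idx <- date_index(toy_dates(600))
  set.seed(21)
  for (i in 1:25) {
    y <- as.numeric(arima.sim(list(ar = 0.9), 600)) + 0.01 * idx$t
    a <- residual_variance_diagnostic(y, time_basis_spec("t:4"), idx)
    b <- residual_variance_diagnostic(y, time_basis_spec("t:4+doy:4"), idx)
    expect_gte(b$r_squared + 1e-10, a$r_squared)
    expect_lte(b$residual_variance,
               a$residual_variance * (600 - 5) / (600 - 9) + 1e-12)
  }
})

test_that("SE inflation ratio follows the root-variance-ratio formula", {
  expect_equal(se_inflation_ratio(1, 4), 2)
  expect_equal(se_inflation_ratio(0.37, 0.37), 1)
  expect_error(se_inflation_ratio(0, 1), "positive")
})

test_that("predicted SE inflation matches model-based Poisson SEs within 25%", {
  set.seed(31)
  n <- 2200
  idx <- date_index(toy_dates(n, "2008-01-01"))
  x <- generate_exposure(idx, concurvity = "low")
  y <- rpois(n, 100)  # outcome unrelated to x: SEs purely design-driven
  da <- residual_variance_diagnostic(x, time_basis_spec("t:4/yr"), idx)
  db <- residual_variance_diagnostic(x, time_basis_spec("10,3,3"), idx)
  predicted <- se_inflation_ratio(da$residual_variance, db$residual_variance)
  se_for <- function(spec) {
    X <- cbind(1, x, build_time_basis(idx, time_basis_spec(spec)))
    f <- glm.fit(X, y, family = poisson())
    p <- f$rank
    sqrt(chol2inv(f$qr$qr[1:p, 1:p])[2, 2])
  }
  observed <- se_for("t:4/yr") / se_for("10,3,3")
  expect_lt(abs(observed - predicted) / predicted, 0.25)
})

test_that("dummy-day columns group flagged dates into contiguous runs", {
  idx <- date_index(toy_dates(60))
  flagged <- idx$date[c(5:9, 20, 40:42)]
  spec <- add_dummy_days(time_basis_spec("t:2"), flagged)
  B <- build_time_basis(idx, spec)
  dev_cols <- grep("dev_run", colnames(B))
  expect_equal(length(dev_cols), 3L)
  expect_equal(colSums(B[, dev_cols]), c(5, 1, 3), ignore_attr = TRUE)
})
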