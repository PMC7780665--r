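#' Fit a constrained distributed-lag Poisson model
#'
#' Fits the log-linear count model
#' \deqn{\log E[Y_t] = \alpha + \sum_{l=l_0}^{l_1} \beta_l X_{t-l} + f(Z) + g(t)}
#' to a daily time series, where the per-lag exposure coefficients are
#' constrained to a smooth curve \eqn{\beta = W\theta} ([lag_constraint()]),
#' `g(t)` is a seasonality/long-term-trend basis ([time_basis_spec()]), and
#' `f(Z)` collects optional covariate terms. Estimation is Poisson maximum
#' likelihood by iteratively reweighted least squares; overdispersion is
#' handled quasi-likelihood style, scaling the covariance by the Pearson
#' dispersion \eqn{\phi = \chi^2_P / (n - k)} (or pinning \eqn{\phi = 1}).
#'
#' Rows with incomplete lag history (the first `max(lag)` days, plus any rows
#' where the outcome or a lagged covariate is missing) are excluded from the
#' likelihood rather than imputed.
#'
#' @param data data frame with columns `date`, the exposure and the outcome
#'   (see `exposure`, `outcome`), e.g. from [simulate_series()] or
#'   [read_timeseries_csv()].
#' @param time_spec a [time_basis_spec()] or a spec string such as
#'   `"10,5,5"` or `"t:4/yr"`.
#' @param lag length-2 integer vector `c(l0, l1)`: the exposure lag window.
#' @param lag_df reduced dimension of the lag constraint; default 5 for
#'   windows of two years or more, 4 for windows of about a year, otherwise
#'   `min(4, window length)`.
#' @param lag_scale `"log"` or `"linear"` knot placement over lag.
#' @param exposure,outcome column names in `data`.
#' @param adjust_lags optional length-2 vector: an *additional* constrained
#'   distributed-lag exposure block (e.g. `c(2, 730)`) included purely as an
#'   adjustment when the window of interest is short.
#' @param adjust_df reduced dimension for the adjustment block.
#' @param covariates optional named list of covariate terms: each element
#'   either `TRUE` (enter the column linearly, unlagged) or a list with
#'   entries `L`, `var_df`, `lag_df` (and optionally `scale`) passed to
#'   [covariate_lag_spline()]. Names must be columns of `data`.
#' @param dispersion `"estimate"` (quasi-Poisson, default) or `"fixed"`
#'   (\eqn{\phi = 1}, plain Poisson standard errors).
#' @return Object of class `"dlm"`. Components include `coefficients`
#'   (reduced scale: intercept, `theta`, covariate and basis coefficients),
#'   `vcov` (dispersion-scaled), `dispersion`, `constraint`, `theta_idx`,
#'   `n_used`, `converged`, `deviance`, `fitted` and `y` on the used rows.
#'   Use [cumulative_effect()] for the overall cumulative coefficient and
#'   per-lag curve, and the usual `coef`, `vcov`, `summary`, `predict`,
#'   `residuals`, `plot` methods.
#' @examples
#' cfg <- sim_config(n_years = 2, lag_max = 60, burn_in_days = 60)
#' dat <- simulate_series(cfg, seed = 1)
#' fit <- dlm(dat, time_spec = "4,2,2", lag = c(0, 60), lag_df = 4)
#' cumulative_effect(fit)
#' @export
dlm <- function(data, time_spec = time_basis_spec(), lag = c(0, 730),
                lag_df = NULL, lag_scale = "log",
                exposure = "exposure", outcome = "outcome",
                adjust_lags = NULL, adjust_df = 5,
                covariates = NULL,
                dispersion = c("estimate", "fixed")) {
  dispersion <- match.arg(dispersion)
  if (is.character(time_spec)) time_spec <- time_basis_spec(time_spec)
  stopifnot(is.data.frame(data), "date" %in% names(data))
  for (col in c(exposure, outcome))
    if (!col %in% names(data)) stop(sprintf("column '%s' not found", col), call. = FALSE)
  x <- data[[exposure]]
  y <- data[[outcome]]
  if (any(y < 0 | (is.finite(y) & y != round(y)), na.rm = TRUE))
    stop("outcome must contain non-negative integer counts", call. = FALSE)
  idx <- date_index(data$date)
  n <- nrow(idx)

  lag <- as.integer(lag)
  if (length(lag) != 2L || lag[1L] < 0L || lag[2L] < lag[1L])
    stop("'lag' must be c(l0, l1) with 0 <= l0 <= l1", call. = FALSE)
  lags <- lag[1L]:lag[2L]
  if (is.null(lag_df)) {
    nl <- length(lags)
    lag_df <- if (nl >= 600L) 5L else if (nl >= 200L) 4L else min(4L, nl)
  }
  W <- constraint_basis(lags, as.integer(lag_df), lag_scale)
  lag_all <- lag_matrix(x, lag[2L])
  Q <- lag_all[, lags + 1L, drop = FALSE] %*% W
  colnames(Q) <- paste0("exp.theta", seq_len(ncol(Q)))

  Q2 <- NULL; W2 <- NULL; lags2 <- NULL
  if (!is.null(adjust_lags)) {
    adjust_lags <- as.integer(adjust_lags)
    lags2 <- adjust_lags[1L]:adjust_lags[2L]
    W2 <- constraint_basis(lags2, as.integer(min(adjust_df, length(lags2))), lag_scale)
    la2 <- lag_matrix(x, adjust_lags[2L])
    Q2 <- la2[, lags2 + 1L, drop = FALSE] %*% W2
    colnames(Q2) <- paste0("adj.theta", seq_len(ncol(Q2)))
  }

  Zb <- NULL
  if (!is.null(covariates)) {
    zparts <- list()
    for (nm in names(covariates)) {
      if (!nm %in% names(data)) stop(sprintf("covariate column '%s' not found", nm),
                                     call. = FALSE)
      spec_z <- covariates[[nm]]
      if (isTRUE(spec_z)) {
        zb <- matrix(data[[nm]], ncol = 1L, dimnames = list(NULL, nm))
      } else {
        zb <- covariate_lag_spline(data[[nm]], spec_z$L, spec_z$var_df, spec_z$lag_df,
                                   scale = if (is.null(spec_z$scale)) "linear" else spec_z$scale)
        colnames(zb) <- paste0(nm, ".", colnames(zb))
      }
      zparts[[nm]] <- zb
    }
    Zb <- do.call(cbind, zparts)
  }

  # Rows entering the likelihood: full lag history and an observed count.
  # The time basis is then built on those rows, so its knots, per-year df and
  # year reference coding describe the analysis span, not the burn-in.
  pre <- cbind(Q, Q2, Zb)
  used <- stats::complete.cases(pre) & is.finite(y)
  idx_used <- idx[used, , drop = FALSE]
  B <- build_time_basis(idx_used, time_spec)
  Xu <- cbind(`(Intercept)` = 1, pre[used, , drop = FALSE], B)
  yu <- y[used]
  n_used <- sum(used)
  if (n_used <= ncol(Xu))
    stop(sprintf("design has %d columns but only %d usable rows", ncol(Xu), n_used),
         call. = FALSE)
  if (all(yu == 0)) stop("outcome is identically zero on the usable rows", call. = FALSE)

  theta_idx <- 1L + seq_len(ncol(Q))
  # rank reduction by pivoted QR: aliased columns dropped with a warning,
  # but never from the exposure block of interest
  qx <- qr(Xu)
  if (qx$rank < ncol(Xu)) {
    drop_idx <- sort(qx$pivot[(qx$rank + 1L):ncol(Xu)])
    if (any(drop_idx %in% theta_idx))
      stop("exposure lag basis is collinear with the remaining design; ",
           "reduce lag_df or the time basis", call. = FALSE)
    warning("dropping collinear design column(s): ",
            paste(colnames(Xu)[drop_idx], collapse = ", "), call. = FALSE)
    Xu <- Xu[, -drop_idx, drop = FALSE]
    theta_idx <- match(colnames(Q), colnames(Xu))
  } else {
    theta_idx <- match(colnames(Q), colnames(Xu))
  }

  fit <- suppressWarnings(stats::glm.fit(
    Xu, yu, family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-9, maxit = 100)))
  if (!fit$converged)
    warning("IRLS did not converge within 100 iterations", call. = FALSE)
  mu <- fit$fitted.values
  k <- fit$rank
  pearson <- sum((yu - mu)^2 / mu)
  phi <- if (dispersion == "estimate") pearson / (n_used - k) else 1
  # unscaled covariance from the final weighted QR (cf. summary.glm)
  p1 <- seq_len(k)
  cov_uns <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  piv <- fit$qr$pivot[p1]
  vc <- matrix(NA_real_, ncol(Xu), ncol(Xu),
               dimnames = list(colnames(Xu), colnames(Xu)))
  vc[piv, piv] <- cov_uns * phi

  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(Xu)),
    vcov = vc,
    dispersion = phi,
    dispersion_mode = dispersion,
    theta_idx = theta_idx,
    constraint = list(W = W, lags = lags, d = ncol(W), scale = lag_scale),
    adjust_constraint = if (is.null(W2)) NULL else list(W = W2, lags = lags2),
    n_used = n_used,
    used = used,
    converged = fit$converged,
    deviance = fit$deviance,
    fitted = mu,
    y = yu,
    dates_used = data$date[used],
    time_spec = time_spec,
    rank = k,
    call = match.call()
  ), class = "dlm")
}

#' @export
print.dlm <- function(x, digits = 4, ...) {
  cat("Constrained distributed-lag Poisson model\n")
  cat(sprintf("  lags %d..%d via %d reduced coefficient(s); time basis: %s\n",
              min(x$constraint$lags), max(x$constraint$lags), x$constraint$d,
              if (nchar(x$time_spec$label)) x$time_spec$label else "intercept only"))
  cat(sprintf("  n used = %d, dispersion = %.3f (%s), deviance = %.1f%s\n",
              x$n_used, x$dispersion, x$dispersion_mode, x$deviance,
              if (x$converged) "" else " [NOT CONVERGED]"))
  ce <- cumulative_effect(x)
  cat(sprintf("  overall cumulative coefficient: %.*g (SE %.*g)\n",
              digits, ce$beta_bar, digits, ce$se))
  invisible(x)
}

#' @export
coef.dlm <- function(object, ...) object$coefficients

#' @export
vcov.dlm <- function(object, ...) object$vcov

#' @export
fitted.dlm <- function(object, ...) object$fitted

#' @export
residuals.dlm <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Predictions on the rows used in the fit
#'
#' Returns the fitted linear predictor (`type = "link"`, the predicted log
#' mean) or the fitted mean (`type = "response"`) for the rows that entered
#' the likelihood; `newdata` is not supported because lagged designs cannot
#' be reconstructed from arbitrary new rows.
#'
#' @param object a [dlm()] fit.
#' @param type `"link"` or `"response"`.
#' @param ... unused.
#' @export
predict.dlm <- function(object, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") object$fitted else log(object$fitted)
}

#' @export
simulate.dlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.dlm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, dispersion = object$dispersion,
                 n_used = object$n_used, deviance = object$deviance,
                 cumulative = cumulative_effect(object), call = object$call),
            class = "summary.dlm")
}

#' @export
print.summary.dlm <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("n used = %d, dispersion = %.3f, deviance = %.1f\n\n",
              x$n_used, x$dispersion, x$deviance))
  stats::printCoefmat(x$coefficients[seq_len(min(10L, nrow(x$coefficients))), ,
                                     drop = FALSE])
  if (nrow(x$coefficients) > 10L)
    cat(sprintf("  ... %d further coefficients not shown\n",
                nrow(x$coefficients) - 10L))
  cat("\n")
  print(x$cumulative)
  invisible(x)
}

#' Overall cumulative effect and per-lag curve
#'
#' Sums the constrained per-lag coefficients over a lag window:
#' \eqn{\bar\beta = c' W \hat\theta} with `c` the 0/1 selector over the
#' window, variance \eqn{c' W V_\theta W' c} (delta method), Wald 95\%
#' interval, and the conventional reporting scale
#' `percent_increase_per_10 = 100 (exp(10 \bar\beta) - 1)` for an exposure
#' measured in micrograms per cubic metre.
#'
#' @param fit a [dlm()] object.
#' @param lag_range length-2 vector within the fitted lag window; default the
#'   full window.
#' @return Object of class `"cumulative_effect"`: `beta_bar`, `se`, `ci95`,
#'   `percent_increase_per_10` (with its own CI), and `lag_curve` (data frame
#'   of per-lag estimates with pointwise 95\% intervals).
#' @export
cumulative_effect <- function(fit, lag_range = NULL) {
  stopifnot(inherits(fit, "dlm"))
  theta <- fit$coefficients[fit$theta_idx]
  vth <- fit$vcov[fit$theta_idx, fit$theta_idx, drop = FALSE]
  cumulative_from_theta(theta, vth, fit$constraint$W, fit$constraint$lags, lag_range)
}

# Shared core for single fits and pooled second-stage estimates.
cumulative_from_theta <- function(theta, vtheta, W, lags, lag_range = NULL) {
  if (is.null(lag_range)) lag_range <- range(lags)
  if (lag_range[1L] < min(lags) || lag_range[2L] > max(lags) ||
      lag_range[1L] > lag_range[2L])
    stop(sprintf("lag_range must lie within %d..%d", min(lags), max(lags)),
         call. = FALSE)
  sel <- lags >= lag_range[1L] & lags <= lag_range[2L]
  beta <- drop(W %*% theta)
  vbeta <- W %*% vtheta %*% t(W)
  cw <- colSums(W[sel, , drop = FALSE])
  beta_bar <- sum(cw * theta)
  se <- sqrt(drop(t(cw) %*% vtheta %*% cw))
  ci <- beta_bar + c(-1, 1) * 1.96 * se
  se_l <- sqrt(pmax(diag(vbeta), 0))
  structure(list(
    beta_bar = beta_bar, se = se, ci95 = ci,
    percent_increase_per_10 = 100 * (exp(10 * beta_bar) - 1),
    pi10_ci95 = 100 * (exp(10 * ci) - 1),
    lag_range = lag_range,
    lag_curve = data.frame(lag = lags, estimate = beta, se = se_l,
                           lower = beta - 1.96 * se_l, upper = beta + 1.96 * se_l)
  ), class = "cumulative_effect")
}

#' @export
print.cumulative_effect <- function(x, ...) {
  cat(sprintf("Cumulative effect over lags %d..%d\n", x$lag_range[1L], x$lag_range[2L]))
  cat(sprintf("  beta_bar = %.6g (SE %.3g), 95%% CI [%.6g, %.6g]\n",
              x$beta_bar, x$se, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  percent increase per 10 ug/m3: %.2f%% [%.2f, %.2f]\n",
              x$percent_increase_per_10, x$pi10_ci95[1L], x$pi10_ci95[2L]))
  invisible(x)
}

#' Plot the estimated lag-response curve
#'
#' @param x a [dlm()] fit.
#' @param lag_range optional window passed to [cumulative_effect()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.dlm <- function(x, lag_range = NULL, ...) {
  ce <- cumulative_effect(x, lag_range)
  lc <- ce$lag_curve
  graphics::plot(lc$lag, lc$estimate, type = "l",
                 xlab = "lag (days)", ylab = "coefficient per unit exposure", ...)
  graphics::lines(lc$lag, lc$lower, lty = 2)
  graphics::lines(lc$lag, lc$upper, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(ce)
}
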