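#' Specify an adjustment method for a simulation study
#'
#' @param label unique method label.
#' @param time_spec a [time_basis_spec()] or spec string.
#' @param lag exposure lag window `c(l0, l1)`.
#' @param lag_df reduced dimension of the lag constraint (`NULL` for the
#'   [dlm()] default).
#' @param adjust_lags,adjust_df optional long-lag adjustment block, as in
#'   [dlm()].
#' @return Object of class `"method_spec"`.
#' @export
method_spec <- function(label, time_spec, lag = c(0, 730), lag_df = NULL,
                        adjust_lags = NULL, adjust_df = 5) {
  if (is.character(time_spec)) time_spec <- time_basis_spec(time_spec)
  structure(list(label = label, time_spec = time_spec, lag = lag,
                 lag_df = lag_df, adjust_lags = adjust_lags,
                 adjust_df = adjust_df),
            class = "method_spec")
}

# The four adjustment methods of the headline comparison.
default_methods <- function(lag = c(0, 730), lag_df = 5) {
  list(method_spec("unadjusted", "", lag, lag_df),
       method_spec("ncs_t_4yr", "t:4/yr", lag, lag_df),
       method_spec("ncs_t_10yr", "t:10/yr", lag, lag_df),
       method_spec("10,5,5", "10,5,5", lag, lag_df))
}

# Fit one method on one replicate; NULL if the fit fails to converge.
# Collinear-column warnings are tolerated (the fit is still valid after
# rank reduction); non-convergence is not.
fit_method <- function(dat, m, dispersion) {
  fit <- suppressWarnings(
    dlm(dat, time_spec = m$time_spec, lag = m$lag, lag_df = m$lag_df,
        adjust_lags = m$adjust_lags, adjust_df = m$adjust_df,
        dispersion = dispersion))
  if (!fit$converged) return(NULL)
  cumulative_effect(fit, lag_range = m$lag)
}

# Replicate-level summaries shared by run_study and the confounding study.
summarize_estimates <- function(est, se, covered, truth) {
  ok <- is.finite(est) & is.finite(se)
  list(bias_percent = 100 * (mean(est[ok]) - truth) / truth,
       sd_estimates = stats::sd(est[ok]) * 10,   # per 10 ug/m3
       coverage_percent = 100 * mean(covered[ok]),
       n_effective = sum(ok), truth = truth)
}

#' Monte-Carlo evaluation of adjustment methods
#'
#' For each replicate, simulates a series under `config`, fits every method,
#' and records the overall cumulative coefficient and its Wald 95\% interval.
#' Summaries per method: percent bias of the mean estimate, SD of estimates
#' (reported per 10 units of exposure), and nominal 95\% CI coverage.
#' Replicates where a fit fails or does not converge are excluded from that
#' method's summaries and counted.
#'
#' @param config a [sim_config()].
#' @param methods list of [method_spec()]s; default the four stock methods.
#' @param n_reps replicates (default `config$n_reps`).
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param dispersion passed to [dlm()].
#' @param keep_lag_curves if `TRUE`, per-replicate lag curves are retained
#'   (attribute `lag_curves`, one matrix per method) for
#'   [lag_curve_summary()].
#' @return A data frame of class `"evaluation_result"` with one row per
#'   method: `method`, `bias_percent`, `sd_estimates`, `coverage_percent`,
#'   `n_effective`, `truth`.
#' @export
run_study <- function(config, methods = NULL, n_reps = config$n_reps,
                      seed = 1, dispersion = c("estimate", "fixed"),
                      keep_lag_curves = FALSE) {
  dispersion <- match.arg(dispersion)
  if (is.null(methods))
    methods <- default_methods(lag = c(0, config$lag_max))
  labels <- vapply(methods, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("method labels must be unique", call. = FALSE)
  nm <- length(methods)
  est <- se <- matrix(NA_real_, n_reps, nm, dimnames = list(NULL, labels))
  covered <- matrix(NA, n_reps, nm)
  curves <- if (keep_lag_curves) vector("list", nm) else NULL
  truth <- NA_real_
  for (r in seq_len(n_reps)) {
    dat <- simulate_series(config, seed = seed + r)
    truth <- attr(dat, "truth")$beta_bar
    for (j in seq_len(nm)) {
      ce <- tryCatch(fit_method(dat, methods[[j]], dispersion),
                     error = function(e) NULL)
      if (is.null(ce)) next
      est[r, j] <- ce$beta_bar
      se[r, j] <- ce$se
      covered[r, j] <- ce$ci95[1L] <= truth && truth <= ce$ci95[2L]
      if (keep_lag_curves)
        curves[[j]] <- rbind(curves[[j]], ce$lag_curve$estimate)
    }
  }
  rows <- lapply(seq_len(nm), function(j) {
    s <- summarize_estimates(est[, j], se[, j], covered[, j], truth)
    data.frame(method = labels[j], bias_percent = s$bias_percent,
               sd_estimates = s$sd_estimates,
               coverage_percent = s$coverage_percent,
               n_effective = s$n_effective, truth = s$truth)
  })
  out <- do.call(rbind, rows)
  if (keep_lag_curves) {
    names(curves) <- labels
    attr(out, "lag_curves") <- curves
  }
  attr(out, "estimates") <- est
  attr(out, "n_reps") <- n_reps
  class(out) <- c("evaluation_result", class(out))
  out
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo evaluation (%d replicates, truth beta_bar = %g)\n",
              attr(x, "n_reps"), x$truth[1L]))
  y <- data.frame(method = x$method,
                  `bias %` = sprintf("%.1f", x$bias_percent),
                  `SD (per 10)` = sprintf("%.3f", x$sd_estimates),
                  `coverage %` = sprintf("%.1f", x$coverage_percent),
                  n = x$n_effective, check.names = FALSE)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Confounding of short-lag estimates by long-lag exposure
#'
#' Fits the two-day moving-average model (a single coefficient over lags
#' 0--1) with and without an additional constrained distributed-lag block
#' over lags `2..L`, and reports the percent bias of the lag 0--1 cumulative
#' estimate against the generator's true `beta_0 + beta_1`, per time basis.
#' Quantifies whether cumulative long-term exposure (and displacement) acts
#' as a confounder of the short-term association.
#'
#' @param config a [sim_config()]; the pattern should carry long-lag mass
#'   for the experiment to be informative.
#' @param time_specs named list (or character vector) of time-basis specs.
#' @param n_reps replicates.
#' @param seed base seed.
#' @param adjust_df reduced dimension for the lag `2..L` block.
#' @param dispersion passed to [dlm()].
#' @return Data frame with one row per time spec and adjustment status:
#'   `time_spec`, `adjusted`, `bias_percent`, `sd_estimates`, `n_effective`,
#'   `truth`.
#' @export
confounding_experiment <- function(config, time_specs = list("t:10/yr"),
                                   n_reps = 100, seed = 1, adjust_df = 5,
                                   dispersion = c("estimate", "fixed")) {
  dispersion <- match.arg(dispersion)
  if (is.character(time_specs)) time_specs <- as.list(time_specs)
  spec_labels <- vapply(time_specs, function(s)
    if (is.character(s)) s else s$label, character(1L))
  ns <- length(time_specs)
  L <- config$lag_max
  est <- array(NA_real_, c(n_reps, ns, 2L))
  truth <- NA_real_
  for (r in seq_len(n_reps)) {
    dat <- simulate_series(config, seed = seed + r)
    truth <- sum(attr(dat, "truth")$pattern$observable[1:2])
    for (j in seq_len(ns)) {
      for (a in 1:2) {
        ce <- tryCatch(
          fit_method(dat, method_spec("m", time_specs[[j]], lag = c(0, 1),
                                      lag_df = 1,
                                      adjust_lags = if (a == 2L) c(2, L) else NULL,
                                      adjust_df = adjust_df),
                     dispersion),
          error = function(e) NULL)
        if (!is.null(ce)) est[r, j, a] <- ce$beta_bar
      }
    }
  }
  rows <- list()
  for (j in seq_len(ns)) for (a in 1:2) {
    e <- est[, j, a]; ok <- is.finite(e)
    rows[[length(rows) + 1L]] <- data.frame(
      time_spec = spec_labels[j], adjusted = a == 2L,
      bias_percent = 100 * (mean(e[ok]) - truth) / truth,
      sd_estimates = stats::sd(e[ok]) * 10,
      n_effective = sum(ok), truth = truth)
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- est
  out
}

#' Summarize estimated lag curves across replicates
#'
#' @param curves matrix of per-replicate lag curves (replicates in rows,
#'   lags `0..L` in columns), e.g. from `run_study(keep_lag_curves = TRUE)`.
#' @param truth a [make_lag_pattern()] whose `observable` curve is the
#'   generating truth.
#' @return Data frame per lag: pointwise `mean`, empirical SE of the mean
#'   curve, 2.5/97.5 percentile `lower`/`upper` envelope, `truth`, and
#'   `rmse` across replicates.
#' @export
lag_curve_summary <- function(curves, truth) {
  stopifnot(inherits(truth, "lag_pattern"))
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (ncol(curves) != truth$L + 1L)
    stop("lag curve length does not match the truth pattern", call. = FALSE)
  tr <- truth$observable
  data.frame(
    lag = 0:truth$L,
    mean = colMeans(curves),
    se = apply(curves, 2L, stats::sd) / sqrt(nrow(curves)),
    lower = apply(curves, 2L, stats::quantile, probs = 0.025),
    upper = apply(curves, 2L, stats::quantile, probs = 0.975),
    truth = tr,
    rmse = sqrt(colMeans(sweep(curves, 2L, tr)^2))
  )
}

#' Scaled replication of the headline simulation comparison
#'
#' Runs the full factorial of simulation scenarios (low/high exposure
#' concurvity crossed with lag patterns 1 and 2) for the four stock
#' adjustment methods (no adjustment; running-time splines with 4 and 10 df
#' per year; the day-of-year + year + week + month combination "10,5,5"),
#' summarizing percent bias, SD of estimates per 10 units and 95\% CI
#' coverage of the overall cumulative coefficient.
#'
#' @param n_reps replicates per scenario.
#' @param n_years analysis years per replicate.
#' @param seed base seed.
#' @param lag_max,lag_df exposure lag window and constraint dimension.
#' @param dispersion passed to [dlm()].
#' @return Data frame of class `"table2_result"`: one row per scenario and
#'   method with `concurvity`, `pattern`, `method`, `bias_percent`,
#'   `sd_estimates`, `coverage_percent`, `n_effective`, `truth`.
#' @export
reproduce_table2 <- function(n_reps = 200, n_years = 8, seed = 1,
                             lag_max = 730, lag_df = 5,
                             dispersion = c("estimate", "fixed")) {
  dispersion <- match.arg(dispersion)
  scen <- expand.grid(concurvity = c("low", "high"), pattern = c(1, 2),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(scen))) {
    cfg <- sim_config(n_years = n_years, burn_in_days = lag_max,
                      concurvity = scen$concurvity[i], pattern = scen$pattern[i],
                      lag_max = lag_max)
    res <- run_study(cfg, default_methods(lag = c(0, lag_max), lag_df = lag_df),
                     n_reps = n_reps, seed = seed + 1000L * i,
                     dispersion = dispersion)
    rows[[i]] <- cbind(concurvity = scen$concurvity[i], pattern = scen$pattern[i],
                       as.data.frame(res))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table2_result", "data.frame")
  out
}

#' @export
print.table2_result <- function(x, ...) {
  y <- data.frame(concurvity = x$concurvity, pattern = x$pattern,
                  method = x$method,
                  `bias %` = sprintf("%.1f", x$bias_percent),
                  `SD (per 10)` = sprintf("%.3f", x$sd_estimates),
                  `coverage %` = sprintf("%.1f", x$coverage_percent),
                  n = x$n_effective, check.names = FALSE)
  print(y, row.names = FALSE)
  invisible(x)
}
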