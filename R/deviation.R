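#' Detect days where two fitted seasonal patterns diverge
#'
#' Compares the predicted log daily means of two models (typically a
#' combination basis versus an aggressive running-time spline, which tracks
#' irregular deviations from the usual seasonal shape more closely). Days
#' where `|A_t - B_t|` exceeds the given empirical percentile are flagged and
#' grouped into contiguous runs; the runs can be re-entered into the model as
#' dummy variables for a sensitivity re-fit.
#'
#' @param pred_a,pred_b predicted log-mean series of equal length.
#' @param percentile cut-off percentile of `|A_t - B_t|` in `(0, 100]`
#'   (linear-interpolation, type-7 quantile); days strictly above the cut-off
#'   are flagged, so `percentile = 100` flags nothing.
#' @param dates optional `Date` vector aligned with the predictions; enables
#'   `flagged_dates` and date-labelled runs.
#' @return Object of class `"deviation_set"`: `abs_diff`, `cutoff_percentile`,
#'   `cutoff`, `flagged` (logical), `flagged_dates`, and `runs` (data frame
#'   with `start`, `end`, `length` in day positions or dates).
#' @export
detect_deviations <- function(pred_a, pred_b, percentile, dates = NULL) {
  if (length(pred_a) != length(pred_b))
    stop("prediction series must have equal length", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("'percentile' must be in (0, 100]", call. = FALSE)
  d <- abs(pred_a - pred_b)
  cutoff <- as.numeric(stats::quantile(d, percentile / 100, type = 7, names = FALSE))
  flagged <- d > cutoff
  runs <- flag_runs(flagged)
  flagged_dates <- NULL
  if (!is.null(dates)) {
    stopifnot(length(dates) == length(pred_a))
    flagged_dates <- as.Date(dates)[flagged]
    if (nrow(runs)) {
      runs$start_date <- as.Date(dates)[runs$start]
      runs$end_date <- as.Date(dates)[runs$end]
    }
  }
  structure(list(abs_diff = d, cutoff_percentile = percentile, cutoff = cutoff,
                 flagged = flagged, flagged_dates = flagged_dates, runs = runs),
            class = "deviation_set")
}

flag_runs <- function(flagged) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' @export
print.deviation_set <- function(x, ...) {
  cat(sprintf("<deviation_set> %d day(s) above the %gth percentile (cutoff %.4g), %d run(s)\n",
              sum(x$flagged), x$cutoff_percentile, x$cutoff, nrow(x$runs)))
  invisible(x)
}

#' Sensitivity of the cumulative effect to seasonality-deviation dummies
#'
#' Fits the model under basis A and basis B, flags days where the two
#' predicted seasonal patterns deviate (at each cut-off percentile of the
#' grid), augments basis A with one dummy variable per contiguous flagged
#' run, and re-fits. A stable cumulative coefficient across the grid
#' indicates that the A-basis adjustment was already sufficient.
#'
#' @param data daily series, as for [dlm()].
#' @param spec_a,spec_b time-basis specs (strings or [time_basis_spec()]);
#'   A is the working model, B the deviation-sensitive comparator.
#' @param percentiles cut-off grid, default `seq(98, 80, by = -2)`.
#' @param ... further arguments to [dlm()] (lag window, covariates, ...).
#' @return Data frame per percentile: `percentile`, `n_flagged`, `n_runs`,
#'   `beta_bar`, `se`, `percent_increase_per_10`; attribute `base` holds the
#'   unaugmented A fit's cumulative effect, and attribute `range` the spread
#'   of `beta_bar` across the grid.
#' @export
deviation_sensitivity <- function(data, spec_a, spec_b,
                                  percentiles = seq(98, 80, by = -2), ...) {
  fit_a <- dlm(data, time_spec = spec_a, ...)
  fit_b <- dlm(data, time_spec = spec_b, ...)
  if (!identical(fit_a$dates_used, fit_b$dates_used))
    stop("the two fits use different rows; align lag windows", call. = FALSE)
  A <- predict(fit_a, type = "link")
  B <- predict(fit_b, type = "link")
  base_ce <- cumulative_effect(fit_a)
  spec_a_obj <- if (is.character(spec_a)) time_basis_spec(spec_a) else spec_a
  rows <- list()
  for (p in percentiles) {
    row <- tryCatch({
      ds <- detect_deviations(A, B, p, dates = fit_a$dates_used)
      if (sum(ds$flagged) == 0L) {
        ce <- base_ce
        nruns <- 0L
      } else {
        aug <- add_dummy_days(spec_a_obj, ds$flagged_dates)
        fit <- suppressWarnings(dlm(data, time_spec = aug, ...))
        ce <- cumulative_effect(fit)
        nruns <- nrow(ds$runs)
      }
      data.frame(percentile = p, n_flagged = sum(ds$flagged), n_runs = nruns,
                 beta_bar = ce$beta_bar, se = ce$se,
                 percent_increase_per_10 = ce$percent_increase_per_10)
    }, error = function(e) {
      warning(sprintf("cut-off %g failed: %s", p, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base_ce
  attr(out, "range") <- range(out$beta_bar)
  out
}
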