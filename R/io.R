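#' Validate a daily time-series table
#'
#' Checks that a data frame has `date`, exposure and outcome columns, that
#' dates are consecutive calendar days without gaps, and that counts are
#' non-negative integers (`NA` allowed, e.g. on burn-in days without full
#' lag history). Extra columns are treated as covariates.
#'
#' @param data data frame.
#' @param exposure,outcome column names.
#' @return The validated data frame with class `"timeseries_table"`.
#' @export
timeseries_table <- function(data, exposure = "exposure", outcome = "outcome") {
  stopifnot(is.data.frame(data))
  for (col in c("date", exposure, outcome))
    if (!col %in% names(data))
      stop(sprintf("required column '%s' is missing", col), call. = FALSE)
  dates <- as.Date(data$date)
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop(sprintf("unparseable date(s) at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (length(dates) > 1L) {
    step <- as.integer(diff(dates))
    if (any(step != 1L)) {
      i <- which(step != 1L)
      gaps <- sprintf("%s to %s", format(dates[i]), format(dates[i + 1L]))
      stop("calendar gap(s) in the series: ",
           paste(utils::head(gaps, 5L), collapse = "; "), call. = FALSE)
    }
  }
  y <- data[[outcome]]
  bad <- which(is.finite(y) & (y < 0 | y != round(y)))
  if (length(bad))
    stop(sprintf("outcome must be non-negative integer counts; offending row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  if (!is.numeric(data[[exposure]]))
    stop(sprintf("exposure column '%s' must be numeric", exposure), call. = FALSE)
  data$date <- dates
  if (!inherits(data, "timeseries_table"))
    class(data) <- c("timeseries_table", class(data))
  data
}

#' Read a daily time-series CSV
#'
#' Expects columns `date` (ISO-8601), `exposure` and `outcome`; any further
#' columns are kept as covariates. The table is validated with
#' [timeseries_table()]: calendar gaps and non-integer counts are reported
#' as errors naming the offending rows.
#'
#' @param path CSV file.
#' @param exposure,outcome column names.
#' @return A `"timeseries_table"` data frame.
#' @export
read_timeseries_csv <- function(path, exposure = "exposure", outcome = "outcome") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  timeseries_table(df, exposure = exposure, outcome = outcome)
}

#' Write a daily time-series CSV
#'
#' Mirror of [read_timeseries_csv()]: dates are written ISO-8601 and the
#' round trip is lossless up to numeric printing precision (15 significant
#' digits).
#'
#' @param data a time-series data frame.
#' @param path output file.
#' @export
write_timeseries_csv <- function(data, path) {
  out <- as.data.frame(data)
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients, the (row-major) covariance, dispersion, the lag
#' constraint, the time-basis label and the fitted log-mean series — enough
#' to pool the fit ([read_city_estimate()]) or run the deviation procedure
#' without the original data.
#'
#' @param fit a [dlm()] fit.
#' @param path output JSON file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dlm"))
  obj <- list(
    coefficients = as.list(fit$coefficients),
    vcov = as.vector(t(fit$vcov)),
    vcov_dim = ncol(fit$vcov),
    dispersion = fit$dispersion,
    theta_idx = fit$theta_idx,
    lags = range(fit$constraint$lags),
    lag_d = fit$constraint$d,
    lag_scale = fit$constraint$scale,
    time_spec = fit$time_spec$label,
    n_used = fit$n_used,
    converged = fit$converged,
    dates_used = format(fit$dates_used, "%Y-%m-%d"),
    predicted_log_mean = log(fit$fitted)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized fit
#'
#' @param path JSON file written by [write_fit_json()].
#' @return A list mirroring the serialized fields, with `vcov` restored to a
#'   matrix and `dates_used` to `Date`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$vcov <- matrix(obj$vcov, obj$vcov_dim, obj$vcov_dim, byrow = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$dates_used <- as.Date(obj$dates_used)
  obj
}

#' @rdname read_fit_json
#' @param label city label for the resulting estimate.
#' @return `read_city_estimate()`: a [city_estimate()] built from the stored
#'   exposure coefficient block.
#' @export
read_city_estimate <- function(path, label = path) {
  obj <- read_fit_json(path)
  city_estimate(obj$coefficients[obj$theta_idx],
                obj$vcov[obj$theta_idx, obj$theta_idx, drop = FALSE],
                label = label)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML fields mirror [sim_config()] argument-for-argument; baseline
#' models are nested mappings with the [baseline_model()] fields.
#'
#' @param path YAML file.
#' @return `sim_config_from_yaml()`: a [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bl <- function(b) if (is.null(b)) NULL else do.call(baseline_model, b)
  sim_config(
    n_years = y$n_years %||% 8,
    burn_in_days = y$burn_in_days %||% 730,
    concurvity = y$concurvity %||% "low",
    pattern = y$pattern %||% 1,
    lag_max = y$lag_max %||% 730,
    target_rate = y$target_rate %||% 100,
    target_cumulative = y$target_cumulative,
    exposure_baseline = bl(y$exposure_baseline),
    outcome_baseline = bl(y$outcome_baseline),
    start_date = as.Date(y$start_date %||% "2002-01-01"),
    n_reps = y$n_reps %||% 200,
    seed = y$seed
  )
}

#' @rdname sim_config_from_yaml
#' @param config a [sim_config()].
#' @export
sim_config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$start_date <- format(obj$start_date, "%Y-%m-%d")
  obj$exposure_baseline <- unclass(obj$exposure_baseline)
  obj$outcome_baseline <- unclass(obj$outcome_baseline)
  # full double precision so a re-read config regenerates identical series
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
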