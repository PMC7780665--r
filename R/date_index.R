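#' Calendar index for a daily time series
#'
#' Expands a gap-free sequence of daily dates into the derived time variables
#' used by the seasonality/trend bases: a running day index `t`, day-of-year
#' `doy` on a fixed 1--365 scale, running week and month orders, and the
#' calendar year.
#'
#' Leap days are handled by assigning February 29 the fractional position
#' 59.5 (between February 28 and March 1) and shifting later days down by
#' one, so `doy` always lies in \[1, 365\] and the same calendar day falls on
#' the same `doy` in every year. This keeps a day-of-year spline phase-aligned
#' across leap and common years.
#'
#' @param dates a `Date` vector, strictly increasing with step exactly one day.
#' @return A data frame of class `"date_index"` with columns `date`, `t`
#'   (1-based day index), `doy`, `week_order` (`ceiling(t/7)`), `month_order`
#'   (count of distinct year-month pairs up to each date), and `year`.
#' @examples
#' idx <- date_index(seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day"))
#' idx$doy[idx$date == as.Date("2004-02-29")]  # 59.5
#' @export
date_index <- function(dates) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  n <- length(dates)
  if (n < 1L) stop("'dates' is empty", call. = FALSE)
  if (anyNA(dates)) stop("'dates' contains missing values", call. = FALSE)
  if (n > 1L) {
    step <- as.integer(diff(dates))
    if (any(step != 1L)) {
      bad <- which(step != 1L)[1L]
      stop(sprintf("dates must be consecutive days: gap or reversal between %s and %s",
                   dates[bad], dates[bad + 1L]), call. = FALSE)
    }
  }
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  yday <- lt$yday + 1L
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  doy <- ifelse(leap & yday == 60L, 59.5,
                ifelse(leap & yday > 60L, yday - 1L, yday))
  month_key <- year * 12L + lt$mon
  month_order <- cumsum(c(1L, as.integer(diff(month_key) != 0L)))
  out <- data.frame(
    date = dates,
    t = seq_len(n),
    doy = doy,
    week_order = ceiling(seq_len(n) / 7),
    month_order = month_order,
    year = year
  )
  class(out) <- c("date_index", "data.frame")
  out
}

#' @export
print.date_index <- function(x, ...) {
  cat(sprintf("<date_index> %d days: %s to %s (%d year(s))\n",
              nrow(x), format(x$date[1L]), format(x$date[nrow(x)]),
              length(unique(x$year))))
  invisible(x)
}

# Number of years spanned, used for the df-per-year convention.
n_years_of <- function(index) nrow(index) / 365.25
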