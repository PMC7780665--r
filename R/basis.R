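#' Natural cubic spline basis with quantile knots
#'
#' Evaluates a natural cubic spline basis of a given dimension on a numeric
#' variable. Interior knots are placed at equally spaced quantiles of the
#' *distinct* values of `x` (type-7 quantiles); boundary knots at the range.
#' The basis is linear beyond the boundary knots and, together with an
#' intercept, spans all polynomials of degree at most one exactly.
#'
#' @param x numeric vector.
#' @param df basis dimension (number of columns, intercept excluded); `df = 1`
#'   gives a single affine column (a natural spline with no interior knot is
#'   a straight line).
#' @return An `n x df` matrix with attributes `knots` (interior) and
#'   `boundary_knots`.
#' @examples
#' B <- ns_basis(1:100, df = 4)
#' dim(B)
#' @export
ns_basis <- function(x, df) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be numeric without NAs", call. = FALSE)
  df <- as.integer(df)
  if (df < 1L) stop("'df' must be >= 1", call. = FALSE)
  ux <- sort(unique(x))
  if (df > length(ux) - 1L)
    stop(sprintf("df = %d exceeds number of distinct x values minus one (%d)",
                 df, length(ux) - 1L), call. = FALSE)
  bk <- range(ux)
  ik <- if (df >= 2L)
    as.numeric(stats::quantile(ux, probs = seq_len(df - 1L) / df, type = 7, names = FALSE))
  else numeric(0)
  B <- if (length(ik))
    splines::ns(x, knots = ik, Boundary.knots = bk)
  else
    splines::ns(x, df = 1L, Boundary.knots = bk)
  B <- unclass(B)[, , drop = FALSE]
  dimnames(B) <- NULL
  structure(B, knots = ik, boundary_knots = bk)
}

spec_kinds <- c("ncs_time_per_year", "ncs_time_total", "ncs_doy",
                "year_indicator", "ncs_week", "ncs_month", "dummy_days")

#' Specify a seasonality / long-term-trend adjustment basis
#'
#' Parses a compact string grammar into an ordered list of basis components.
#' Components are joined with `+`:
#' \describe{
#'   \item{`t:<p>/yr`}{natural cubic spline of the running day index with
#'     `p` df per year (total df = `round(p * years)`); `p` may be fractional.}
#'   \item{`t:<k>`}{spline of the running day index with `k` total df.}
#'   \item{`doy:<p>`}{spline of day-of-year, so the fitted seasonal shape
#'     repeats identically each year.}
#'   \item{`year`}{indicator (dummy) variables for calendar year,
#'     reference-coded against the first year.}
#'   \item{`week:<q>` / `month:<r>`}{splines of the running week / month
#'     order, capturing between-year drift in seasonality.}
#' }
#' The shorthand `"p,q,r"` expands to `doy:p + year + week:q + month:r`,
#' e.g. `"10,5,5"`. An empty string (or `"none"`) gives an intercept-only
#' (zero-column) adjustment. `ncs_t:` is accepted as a synonym of `t:`.
#'
#' Flagged dates (from [detect_deviations()]) can be attached with
#' [add_dummy_days()]; each contiguous run of flagged dates becomes one 0/1
#' indicator column.
#'
#' @param spec character scalar in the grammar above, or `""`.
#' @param dummy_dates optional `Date` vector of flagged days.
#' @return An object of class `"time_basis_spec"`.
#' @examples
#' time_basis_spec("10,5,5")
#' time_basis_spec("t:4/yr")
#' @export
time_basis_spec <- function(spec = "", dummy_dates = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  comps <- list()
  add <- function(kind, df = NULL, dates = NULL) {
    if (any(vapply(comps, function(c) c$kind == kind, logical(1L))))
      stop(sprintf("component '%s' appears more than once", kind), call. = FALSE)
    if (!is.null(df) && df < 1)
      stop(sprintf("df for '%s' must be >= 1", kind), call. = FALSE)
    comps[[length(comps) + 1L]] <<- list(kind = kind, df = df, dates = dates)
  }
  s <- gsub("[[:space:]]", "", spec)
  if (!(s == "" || tolower(s) == "none")) {
    # shorthand "p,q,r"
    if (grepl("^[0-9.]+,[0-9.]+,[0-9.]+$", s)) {
      v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
      s <- sprintf("doy:%g+year+week:%g+month:%g", v[1L], v[2L], v[3L])
    }
    for (tok in strsplit(s, "+", fixed = TRUE)[[1L]]) {
      if (tok == "year") { add("year_indicator"); next }
      m <- regmatches(tok, regexec("^(ncs_t|t|doy|week|month):([0-9.]+)(/yr)?$", tok))[[1L]]
      if (length(m) == 0L)
        stop(sprintf("cannot parse basis component '%s'", tok), call. = FALSE)
      var <- m[2L]; val <- as.numeric(m[3L]); per_year <- m[4L] == "/yr"
      if (per_year && !var %in% c("t", "ncs_t"))
        stop(sprintf("'/yr' is only valid for 't': '%s'", tok), call. = FALSE)
      kind <- switch(var,
                     t = , ncs_t = if (per_year) "ncs_time_per_year" else "ncs_time_total",
                     doy = "ncs_doy", week = "ncs_week", month = "ncs_month")
      add(kind, df = val)
    }
  }
  if (!is.null(dummy_dates) && length(dummy_dates))
    comps[[length(comps) + 1L]] <- list(kind = "dummy_days", df = NULL,
                                        dates = as.Date(dummy_dates))
  structure(list(components = comps, label = spec), class = "time_basis_spec")
}

#' Attach deviation-dummy dates to a basis specification
#'
#' @param spec a [time_basis_spec()].
#' @param dates `Date` vector of flagged days; contiguous runs each get one
#'   indicator column when the basis is built.
#' @return The augmented specification.
#' @export
add_dummy_days <- function(spec, dates) {
  stopifnot(inherits(spec, "time_basis_spec"))
  if (length(dates) == 0L) return(spec)
  comps <- Filter(function(c) c$kind != "dummy_days", spec$components)
  comps[[length(comps) + 1L]] <- list(kind = "dummy_days", df = NULL,
                                      dates = sort(as.Date(dates)))
  structure(list(components = comps, label = spec$label), class = "time_basis_spec")
}

#' @export
print.time_basis_spec <- function(x, ...) {
  if (length(x$components) == 0L) {
    cat("<time_basis_spec> intercept only\n")
    return(invisible(x))
  }
  lab <- vapply(x$components, function(c) {
    switch(c$kind,
           ncs_time_per_year = sprintf("NCS(t, %gdf/year)", c$df),
           ncs_time_total = sprintf("NCS(t, %gdf)", c$df),
           ncs_doy = sprintf("NCS(doy, %gdf)", c$df),
           year_indicator = "I(year)",
           ncs_week = sprintf("NCS(week, %gdf)", c$df),
           ncs_month = sprintf("NCS(month, %gdf)", c$df),
           dummy_days = sprintf("dummies(%d days)", length(c$dates)))
  }, character(1L))
  cat("<time_basis_spec>", paste(lab, collapse = " + "), "\n")
  invisible(x)
}

#' Build the seasonality / trend design block
#'
#' Evaluates each component of a [time_basis_spec()] on a [date_index()] and
#' concatenates the column blocks. The intercept is *not* included; it is
#' appended by the model-fitting code.
#'
#' @param index a [date_index()].
#' @param spec a [time_basis_spec()].
#' @return An `n x k` matrix with column names and attribute `knots` (a named
#'   list of interior-knot locations per spline component). An empty spec
#'   yields an `n x 0` matrix.
#' @export
build_time_basis <- function(index, spec) {
  stopifnot(inherits(index, "date_index"), inherits(spec, "time_basis_spec"))
  n <- nrow(index)
  blocks <- list(); knots <- list()
  for (comp in spec$components) {
    kind <- comp$kind
    if (kind == "ncs_time_per_year") {
      total <- as.integer(round(comp$df * n_years_of(index)))
      if (total < 1L)
        stop("per-year df rounds to zero total df for this series length", call. = FALSE)
      B <- ns_basis(index$t, total)
      colnames(B) <- sprintf("ncs_t%d", seq_len(ncol(B)))
    } else if (kind == "ncs_time_total") {
      B <- ns_basis(index$t, comp$df)
      colnames(B) <- sprintf("ncs_t%d", seq_len(ncol(B)))
    } else if (kind == "ncs_doy") {
      B <- ns_basis(index$doy, comp$df)
      colnames(B) <- sprintf("ncs_doy%d", seq_len(ncol(B)))
    } else if (kind == "year_indicator") {
      f <- factor(index$year)
      if (nlevels(f) < 2L) {
        warning("single calendar year: year indicator contributes no columns",
                call. = FALSE)
        B <- matrix(numeric(0), n, 0L)
      } else {
        B <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(B) <- sprintf("year%s", levels(f)[-1L])
      }
    } else if (kind == "ncs_week") {
      B <- ns_basis(index$week_order, comp$df)
      colnames(B) <- sprintf("ncs_week%d", seq_len(ncol(B)))
    } else if (kind == "ncs_month") {
      B <- ns_basis(index$month_order, comp$df)
      colnames(B) <- sprintf("ncs_month%d", seq_len(ncol(B)))
    } else if (kind == "dummy_days") {
      B <- dummy_day_columns(index$date, comp$dates)
    } else stop("unknown basis component kind: ", kind, call. = FALSE)
    if (!is.null(attr(B, "knots")) && length(attr(B, "knots")))
      knots[[kind]] <- attr(B, "knots")
    blocks[[length(blocks) + 1L]] <- B
  }
  out <- if (length(blocks)) do.call(cbind, blocks) else matrix(numeric(0), n, 0L)
  if (ncol(out) >= n)
    stop(sprintf("time basis has %d columns for %d observations", ncol(out), n),
         call. = FALSE)
  attr(out, "knots") <- knots
  out
}

# One 0/1 column per contiguous run of flagged dates.
dummy_day_columns <- function(dates, flagged) {
  flagged <- sort(unique(as.Date(flagged)))
  flagged <- flagged[flagged %in% dates]
  n <- length(dates)
  if (length(flagged) == 0L) return(matrix(numeric(0), n, 0L))
  run_id <- cumsum(c(1L, as.integer(diff(flagged) != 1L)))
  B <- matrix(0, n, max(run_id))
  for (r in seq_len(max(run_id)))
    B[dates %in% flagged[run_id == r], r] <- 1
  colnames(B) <- sprintf("dev_run%d", seq_len(ncol(B)))
  B
}

#' Residual-variance overfitting diagnostic
#'
#' Regresses a series (typically a long-term moving average of the exposure)
#' on an intercept plus a candidate adjustment basis by ordinary least
#' squares. A basis that leaves almost no residual exposure variance will
#' inflate the standard error of a long-term effect estimate; comparing
#' residual variances across candidate bases quantifies this before any
#' outcome model is fitted.
#'
#' @param series numeric vector aligned with `index` (NAs allowed; dropped).
#' @param spec a [time_basis_spec()].
#' @param index a [date_index()].
#' @return A list with `residual_variance` (denominator `n - k - 1`, `k` the
#'   number of retained basis columns), `r_squared` (percent), and `dropped`
#'   (labels of collinear columns removed, if any).
#' @seealso [se_inflation_ratio()]
#' @export
residual_variance_diagnostic <- function(series, spec, index) {
  stopifnot(length(series) == nrow(index))
  B <- build_time_basis(index, spec)
  keep <- is.finite(series)
  y <- series[keep]
  X <- cbind(`(Intercept)` = 1, B[keep, , drop = FALSE])
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1L):ncol(X)]
    dropped <- colnames(X)[drop_idx]
    warning("dropping collinear basis column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  k <- ncol(X) - 1L
  list(residual_variance = rss / (length(y) - k - 1L),
       r_squared = 100 * (1 - rss / tss),
       dropped = dropped)
}

#' Predicted standard-error inflation between two adjustment bases
#'
#' Given residual variances of the exposure series under basis A (the more
#' aggressive adjustment, smaller residual variance) and basis B, returns
#' `sqrt(var_b / var_a)`: the multiplicative factor by which the standard
#' error of a single exposure coefficient is predicted to be inflated when A
#' is used instead of B, since that SE scales inversely with the root
#' residual exposure variance.
#'
#' @param residual_variance_a,residual_variance_b positive residual variances
#'   from [residual_variance_diagnostic()].
#' @return The predicted SE ratio (a positive scalar).
#' @export
se_inflation_ratio <- function(residual_variance_a, residual_variance_b) {
  if (!is.finite(residual_variance_a) || !is.finite(residual_variance_b) ||
      residual_variance_a <= 0 || residual_variance_b <= 0)
    stop("residual variances must be positive", call. = FALSE)
  sqrt(residual_variance_b / residual_variance_a)
}
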