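#' Lagged exposure design block
#'
#' Builds the `n x (L+1)` matrix whose column `l` holds the exposure lagged
#' by `l` days, `X[t - l]`. The first `L` rows have incomplete lag history
#' and are filled with `NA`; model fitting excludes them from the likelihood.
#'
#' @param x numeric exposure series.
#' @param L maximum lag in days (`L >= 0`, `L < length(x)`).
#' @return Matrix with columns `lag0 ... lagL`.
#' @export
lag_matrix <- function(x, L) {
  n <- length(x)
  L <- as.integer(L)
  if (L < 0L) stop("'L' must be >= 0", call. = FALSE)
  if (L >= n) stop(sprintf("L = %d but series has only %d values", L, n), call. = FALSE)
  M <- matrix(NA_real_, n, L + 1L)
  M[(L + 1L):n, ] <- stats::embed(x, L + 1L)
  colnames(M) <- paste0("lag", 0:L)
  M
}

#' Smoothness constraint for distributed-lag coefficients
#'
#' For long lag windows the `L + 1` per-lag coefficients cannot be estimated
#' freely; they are constrained to a low-dimensional smooth curve over lag,
#' `beta = W theta`, with `W` an intercept column plus a natural cubic spline
#' basis evaluated at the lag values. With `scale = "log"` the spline is
#' evaluated at `log(lag + 1)`, concentrating flexibility at short lags where
#' acute effects and mortality displacement live. `d = L + 1` returns the
#' identity transform (unconstrained model); `d = 1` returns a column of
#' ones (a single coefficient shared by all lags, i.e. a scaled moving
#' average).
#'
#' @param L maximum lag.
#' @param d reduced dimension, `1 <= d <= L + 1`.
#' @param scale `"log"` (default) or `"linear"` placement of spline knots
#'   over lag.
#' @return Object of class `"lag_constraint"`: list with `L`, `d`, `W`
#'   (`(L+1) x d`, full column rank), `lags`, `scale`.
#' @export
lag_constraint <- function(L, d, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  L <- as.integer(L); d <- as.integer(d)
  if (L < 0L) stop("'L' must be >= 0", call. = FALSE)
  if (d < 1L || d > L + 1L)
    stop(sprintf("'d' must be in 1..%d (got %d)", L + 1L, d), call. = FALSE)
  W <- constraint_basis(0:L, d, scale)
  structure(list(L = L, d = d, W = W, lags = 0:L, scale = scale),
            class = "lag_constraint")
}

# Spline-plus-intercept transform evaluated at arbitrary lag values.
# d = number of values returns the identity (unconstrained).
constraint_basis <- function(lags, d, scale = "log") {
  nl <- length(lags)
  if (d == nl) {
    W <- diag(nl)
  } else {
    v <- if (scale == "log") log(lags + 1) else as.numeric(lags)
    W <- if (d == 1L) matrix(1, nl, 1L) else cbind(1, ns_basis(v, d - 1L))
  }
  if (qr(W)$rank < ncol(W)) stop("lag constraint basis is rank deficient", call. = FALSE)
  dimnames(W) <- list(paste0("lag", lags), paste0("theta", seq_len(ncol(W))))
  W
}

#' @export
print.lag_constraint <- function(x, ...) {
  cat(sprintf("<lag_constraint> lags 0..%d -> %d coefficient(s) (%s scale%s)\n",
              x$L, x$d, x$scale,
              if (x$d == x$L + 1L) ", unconstrained" else ""))
  invisible(x)
}

#' Lagged-spline design block for a covariate
#'
#' A simplified lagged covariate surface: the tensor product of a natural
#' cubic spline transform of the covariate value (`var_df` columns) and a
#' smooth lag transform over `0..L_z` (`lag_df` columns). Used to adjust for
#' confounders such as temperature whose effect is both non-linear and
#' distributed over a couple of weeks. With `var_df = lag_df = 1` the block
#' collapses to a single column proportional (up to an affine shift) to the
#' `(L_z+1)`-day moving average of the covariate.
#'
#' @param z numeric covariate series.
#' @param L_z maximum lag for the covariate.
#' @param var_df spline df in the covariate dimension.
#' @param lag_df reduced dimension in the lag direction.
#' @param scale knot scale over lag, as in [lag_constraint()].
#' @return `n x (var_df * lag_df)` matrix; first `L_z` rows are `NA`.
#' @export
covariate_lag_spline <- function(z, L_z, var_df, lag_df, scale = "linear") {
  if (L_z < 0L) stop("'L_z' must be >= 0", call. = FALSE)
  if (var_df < 1L || lag_df < 1L) stop("df arguments must be >= 1", call. = FALSE)
  Bv <- ns_basis(z, var_df)
  W <- constraint_basis(0:L_z, as.integer(lag_df), scale)
  blocks <- lapply(seq_len(ncol(Bv)), function(i) {
    lag_matrix(Bv[, i], L_z) %*% W
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(outer(seq_len(ncol(W)), seq_len(ncol(Bv)),
                                   function(j, i) sprintf("v%d.l%d", i, j)))
  out
}
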