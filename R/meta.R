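#' City-specific reduced coefficient estimate
#'
#' First-stage input to the second-stage pooling: the reduced lag
#' coefficients of one city's [dlm()] fit and their within-city covariance.
#'
#' @param theta numeric vector of reduced coefficients (length d).
#' @param vcov d x d symmetric positive semi-definite covariance.
#' @param label city label.
#' @return Object of class `"city_estimate"`.
#' @seealso [as_city_estimate()] to extract one from a fitted model.
#' @export
city_estimate <- function(theta, vcov, label = "") {
  theta <- as.numeric(theta)
  vcov <- as.matrix(vcov)
  d <- length(theta)
  if (!all(dim(vcov) == d)) stop("vcov dimension does not match theta", call. = FALSE)
  if (max(abs(vcov - t(vcov))) > 1e-8 * max(1, max(abs(vcov))))
    stop("vcov must be symmetric", call. = FALSE)
  if (min(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("vcov must be positive semi-definite", call. = FALSE)
  structure(list(theta = theta, vcov = (vcov + t(vcov)) / 2, label = label),
            class = "city_estimate")
}

#' Extract the reduced-coefficient estimate from a fitted model
#'
#' @param fit a [dlm()] fit.
#' @param label city label.
#' @return A [city_estimate()] holding the exposure `theta` block and its
#'   covariance.
#' @export
as_city_estimate <- function(fit, label = "") {
  stopifnot(inherits(fit, "dlm"))
  city_estimate(fit$coefficients[fit$theta_idx],
                fit$vcov[fit$theta_idx, fit$theta_idx, drop = FALSE],
                label = label)
}

#' Multivariate random-effects pooling of city-specific coefficients
#'
#' Pools city-specific reduced lag coefficient vectors under the two-stage
#' model \eqn{\theta_i \sim N(\theta, S_i + \Psi)} with within-city
#' covariances \eqn{S_i} and between-city covariance \eqn{\Psi}:
#' \describe{
#'   \item{`fixed`}{\eqn{\Psi = 0}; generalized-least-squares pooling
#'     \eqn{\hat\theta = (\sum S_i^{-1})^{-1} \sum S_i^{-1} \theta_i}.}
#'   \item{`mm`}{multivariate method of moments: the weighted dispersion
#'     matrix of the city estimates about the fixed-effect pool is matched
#'     to its expectation (which is linear in \eqn{\Psi}), the resulting
#'     linear system solved, and \eqn{\hat\Psi} projected onto the positive
#'     semi-definite cone; for d = 1 this reduces exactly to the
#'     DerSimonian-Laird estimator with truncation at zero. GLS with weights
#'     \eqn{(S_i + \hat\Psi)^{-1}} then gives the pooled estimate.}
#'   \item{`ml`}{maximum likelihood: the marginal normal likelihood is
#'     maximized over \eqn{\Psi} parameterized by its Cholesky factor
#'     (enforcing positive semi-definiteness), profiling \eqn{\theta} by GLS;
#'     quasi-Newton optimization with multiple starts (zero and the
#'     empirical excess variance).}
#' }
#'
#' @param estimates list of [city_estimate()]s (at least two, common
#'   dimension).
#' @param method `"ml"` (default), `"mm"`, or `"fixed"`.
#' @return Object of class `"pooled_estimate"`: `theta`, `vcov`, `psi`
#'   (between-city covariance), `method`, `n_cities`, and for ML the
#'   maximized `logLik`.
#' @export
pool <- function(estimates, method = c("ml", "mm", "fixed")) {
  method <- match.arg(method)
  m <- length(estimates)
  if (m < 2L) stop("need at least 2 city estimates", call. = FALSE)
  if (!all(vapply(estimates, inherits, logical(1L), "city_estimate")))
    stop("'estimates' must be a list of city_estimate objects", call. = FALSE)
  d <- length(estimates[[1L]]$theta)
  if (!all(vapply(estimates, function(e) length(e$theta), integer(1L)) == d))
    stop("city estimates have differing dimensions", call. = FALSE)
  th <- do.call(rbind, lapply(estimates, `[[`, "theta"))
  S <- lapply(estimates, `[[`, "vcov")
  Winv <- vector("list", m)
  for (i in seq_len(m)) {
    Winv[[i]] <- tryCatch(solve(S[[i]]), error = function(e)
      stop(sprintf("within-city covariance of '%s' (city %d) is singular",
                   estimates[[i]]$label, i), call. = FALSE))
  }

  gls <- function(psi) {
    Wi <- lapply(S, function(s) solve(s + psi))
    A <- Reduce(`+`, Wi)
    b <- Reduce(`+`, Map(function(w, i) w %*% th[i, ], Wi, seq_len(m)))
    V <- solve(A)
    list(theta = drop(V %*% b), vcov = V, Wi = Wi)
  }

  psi <- matrix(0, d, d)
  ll <- NA_real_
  if (method == "mm") {
    psi <- psi_mm(th, S, Winv)
  } else if (method == "ml") {
    fitml <- psi_ml(th, S)
    psi <- fitml$psi
    ll <- fitml$logLik
  }
  g <- gls(psi)
  structure(list(theta = g$theta, vcov = g$vcov, psi = psi, method = method,
                 n_cities = m, logLik = ll, d = d),
            class = "pooled_estimate")
}

# Method of moments: match Q = sum_i W^{1/2} (th_i - th_F)(th_i - th_F)' W^{1/2}
# (W the fixed-effect weights) to E[Q], which is linear in Psi; solve the
# d(d+1)/2 linear system on vech(Psi) and project onto the PSD cone.
psi_mm <- function(th, S, Winv) {
  m <- nrow(th); d <- ncol(th)
  A <- Reduce(`+`, Winv)
  Ainv <- solve(A)
  thF <- drop(Ainv %*% Reduce(`+`, Map(function(w, i) w %*% th[i, ], Winv, seq_len(m))))
  Wh <- lapply(Winv, mat_sqrt)
  Qobs <- matrix(0, d, d)
  for (i in seq_len(m)) {
    r <- th[i, ] - thF
    Qobs <- Qobs + Wh[[i]] %*% tcrossprod(r) %*% Wh[[i]]
  }
  EQ <- function(psi) {
    V <- lapply(S, function(s) s + psi)
    SWV <- Reduce(`+`, Map(function(w, v) w %*% v %*% w, Winv, V))
    out <- matrix(0, d, d)
    for (i in seq_len(m)) {
      Ci <- V[[i]] - V[[i]] %*% Winv[[i]] %*% Ainv - Ainv %*% Winv[[i]] %*% V[[i]] +
        Ainv %*% SWV %*% Ainv
      out <- out + Wh[[i]] %*% Ci %*% Wh[[i]]
    }
    (out + t(out)) / 2
  }
  C0 <- EQ(matrix(0, d, d))
  basis <- list(); rhs_cols <- list()
  idx <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    E <- matrix(0, d, d)
    E[idx[k, 1L], idx[k, 2L]] <- 1
    E[idx[k, 2L], idx[k, 1L]] <- 1
    basis[[k]] <- E
    rhs_cols[[k]] <- vech(EQ(E) - C0)
  }
  Lmat <- do.call(cbind, rhs_cols)
  coefs <- solve(Lmat, vech(Qobs - C0))
  psi <- Reduce(`+`, Map(`*`, basis, coefs))
  psd_project(psi)
}

# ML over the Cholesky factor of Psi, profiling theta by GLS.
psi_ml <- function(th, S) {
  m <- nrow(th); d <- ncol(th)
  npar <- d * (d + 1L) / 2L
  lower_idx <- which(lower.tri(diag(d), diag = TRUE))
  to_psi <- function(par) {
    Lc <- matrix(0, d, d)
    Lc[lower_idx] <- par
    tcrossprod(Lc)
  }
  nll <- function(par) {
    psi <- to_psi(par)
    Wi <- vector("list", m)
    ld <- 0
    for (i in seq_len(m)) {
      V <- S[[i]] + psi
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      ld <- ld + 2 * sum(log(diag(ch)))
      Wi[[i]] <- chol2inv(ch)
    }
    A <- Reduce(`+`, Wi)
    mu <- drop(solve(A, Reduce(`+`, Map(function(w, i) w %*% th[i, ], Wi, seq_len(m)))))
    quad <- 0
    for (i in seq_len(m)) {
      r <- th[i, ] - mu
      quad <- quad + drop(t(r) %*% Wi[[i]] %*% r)
    }
    0.5 * (ld + quad)
  }
  # starts: Psi = 0 and the empirical excess variance
  excess <- psd_project(stats::cov(th) - Reduce(`+`, S) / m)
  starts <- list(rep(0, npar),
                 {ch <- tryCatch(t(chol(excess + 1e-10 * diag(d))),
                                 error = function(e) NULL)
                  if (is.null(ch)) rep(1e-4, npar) else ch[lower_idx]})
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, nll, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("ML optimization failed", call. = FALSE)
  list(psi = psd_project(to_psi(best$par)), logLik = -best$value)
}

#' Log marginal likelihood of the two-stage model at given parameters
#'
#' @param estimates list of [city_estimate()]s.
#' @param theta pooled mean vector.
#' @param psi between-city covariance matrix.
#' @return The multivariate normal log marginal likelihood (constant terms
#'   `-(md/2) log 2 pi` omitted, matching the ML objective used by [pool()]).
#' @export
pooled_logLik <- function(estimates, theta, psi) {
  ll <- 0
  for (e in estimates) {
    V <- e$vcov + psi
    ch <- chol(V)
    r <- e$theta - theta
    ll <- ll - 0.5 * (2 * sum(log(diag(ch))) +
                        drop(t(r) %*% chol2inv(ch) %*% r))
  }
  ll
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

psd_project <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (%s) over %d cities, d = %d\n",
              x$method, x$n_cities, x$d))
  cat("  theta:", format(x$theta, digits = 4), "\n")
  cat("  SE:   ", format(sqrt(diag(x$vcov)), digits = 4), "\n")
  cat(sprintf("  between-city SD (diag):%s\n",
              paste(format(sqrt(pmax(diag(x$psi), 0)), digits = 3), collapse = " ")))
  invisible(x)
}

#' Cumulative effect from a pooled second-stage estimate
#'
#' Applies the same selector/delta-method mapping as [cumulative_effect()]
#' to the pooled reduced coefficients, using the lag constraint shared by
#' the city-specific first-stage models.
#'
#' @param pooled a [pool()] result.
#' @param constraint the first-stage [lag_constraint()] (its `W` must have
#'   `pooled$d` columns).
#' @param lag_range lag window; default the constraint's full window.
#' @return A `"cumulative_effect"` object.
#' @export
pooled_cumulative <- function(pooled, constraint, lag_range = NULL) {
  stopifnot(inherits(pooled, "pooled_estimate"), inherits(constraint, "lag_constraint"))
  if (ncol(constraint$W) != pooled$d)
    stop("constraint dimension does not match the pooled estimate", call. = FALSE)
  cumulative_from_theta(pooled$theta, pooled$vcov, constraint$W,
                        constraint$lags, lag_range)
}
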