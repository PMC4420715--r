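#' Fisher z-transform
#'
#' Maps a correlation in (-1, 1) to the real line via
#' \eqn{z(x) = \frac{1}{2}\log\{(1+x)/(1-x)\}}.  Used as the link function for
#' all partial-autocorrelation regression models in this package.
#'
#' @param x numeric vector with all elements strictly inside (-1, 1).
#' @return numeric vector of transformed values.
#' @seealso [inverse_fisher_z()]
#' @export
#' @examples
#' fisher_z(0.5)
#' inverse_fisher_z(fisher_z(0.9))
fisher_z <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("x must be numeric without NAs")
  if (any(abs(x) >= 1)) stop("fisher_z is only defined on (-1, 1)")
  atanh(x)
}

#' Inverse Fisher z-transform
#'
#' @param z numeric vector of unconstrained values.
#' @return numeric vector in (-1, 1), \eqn{\tanh(z)}.
#' @export
inverse_fisher_z <- function(z) {
  if (!is.numeric(z) || anyNA(z)) stop("z must be numeric without NAs")
  tanh(z)
}

#' Banded partial autocorrelation matrix
#'
#' Container for partial autocorrelations \eqn{\pi(t, t+j)} on a discrete time
#' grid \eqn{1, \dots, T}, banded at lag `a`: entries with \eqn{j > a} are
#' exactly zero.  Each in-band entry can vary independently in (-1, 1); any
#' such configuration induces a positive-definite correlation matrix, which is
#' the point of the parameterization.
#'
#' @param pi a `T` x `T` symmetric numeric matrix; entry `[t, t + j]` holds the
#'   lag-`j` partial autocorrelation.  The diagonal is ignored (stored as 1).
#'   Entries beyond the band must be zero.
#' @param a integer band width, `0 <= a <= T - 1`.
#' @return an object of class `banded_pacf` with fields `T`, `a`, `pi`.
#' @export
banded_pacf <- function(pi, a) {
  if (!is.matrix(pi) || nrow(pi) != ncol(pi)) stop("pi must be a square matrix")
  T_len <- nrow(pi)
  if (T_len < 1) stop("grid length must be positive")
  a <- as.integer(a)
  if (a < 0 || a > T_len - 1) stop("band width a must satisfy 0 <= a <= T - 1")
  if (max(abs(pi - t(pi))) > 1e-12) stop("pi must be symmetric")
  off <- abs(row(pi) - col(pi))
  inband <- off >= 1 & off <= a
  if (any(abs(pi[inband]) >= 1 - 1e-12)) {
    stop("partial autocorrelations must lie strictly inside (-1, 1); ",
         "values within 1e-12 of the boundary are rejected")
  }
  if (a < T_len - 1 && any(pi[off > a] != 0)) {
    stop("entries beyond band a must be exactly zero")
  }
  pim <- pi
  diag(pim) <- 1
  structure(list(T = T_len, a = a, pi = pim), class = "banded_pacf")
}

#' @export
print.banded_pacf <- function(x, ...) {
  cat(sprintf("banded_pacf: T = %d, band a = %d\n", x$T, x$a))
  nz <- sum(abs(x$pi[upper.tri(x$pi)]) > 0)
  cat(sprintf("  %d non-zero partial autocorrelations\n", nz))
  invisible(x)
}

#' Partial autocorrelations to marginal correlations
#'
#' Converts a banded partial autocorrelation matrix to the unique marginal
#' correlation matrix whose lag-j partial autocorrelations (conditional on the
#' intervening grid values) equal the given ones.  Uses the lag-recursive
#' scheme \eqn{\rho(t, t+j) = r_1' R^{-1} r_3 + \pi(t,t+j) D_{t,t+j}}, filling
#' lags \eqn{j = 1, 2, \dots} in order.  The result is positive definite for
#' every valid input.
#'
#' @param p a [banded_pacf()] object.
#' @return a `T` x `T` correlation matrix.
#' @export
pacf_to_corr <- function(p) {
  stopifnot(inherits(p, "banded_pacf"))
  pacf_to_corr_cpp(p$pi, p$a)
}

#' Marginal correlations to partial autocorrelations
#'
#' Inverse of [pacf_to_corr()] up to the requested band: extracts partial
#' autocorrelations \eqn{\pi(t, t+j)} for lags `j <= a` from a correlation
#' matrix, via the regression-residual definition
#' \eqn{\pi = \{\rho(t,t+j) - r_1'R^{-1}r_3\} / D_{t,t+j}}.
#'
#' @param R positive-definite correlation matrix.
#' @param a band width of the output.
#' @return a [banded_pacf()] object.
#' @export
corr_to_pacf <- function(R, a) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("R must be a square matrix")
  T_len <- nrow(R)
  a <- as.integer(a)
  if (a < 0 || a > T_len - 1) stop("band width a must satisfy 0 <= a <= T - 1")
  .check_pd(R)
  pim <- diag(T_len)
  if (a >= 1 && T_len >= 2) {
    for (t in seq_len(T_len - 1)) {
      pim[t, t + 1] <- R[t, t + 1]
      pim[t + 1, t] <- R[t, t + 1]
    }
  }
  if (a >= 2) {
    for (j in 2:a) {
      for (t in seq_len(T_len - j)) {
        mid <- (t + 1):(t + j - 1)
        Rm <- R[mid, mid, drop = FALSE]
        r1 <- R[t, mid]
        r3 <- R[t + j, mid]
        s1 <- solve(Rm, r1)
        s3 <- solve(Rm, r3)
        D <- sqrt(max(1 - sum(r1 * s1), 0)) * sqrt(max(1 - sum(r3 * s3), 0))
        pim[t, t + j] <- (R[t, t + j] - sum(r1 * s3)) / D
        pim[t + j, t] <- pim[t, t + j]
      }
    }
  }
  diag(pim) <- 1
  banded_pacf(pim, a)
}

# error with the index of the first non-positive-definite leading minor
.check_pd <- function(R) {
  for (k in seq_len(nrow(R))) {
    ok <- tryCatch({
      chol(R[1:k, 1:k, drop = FALSE])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("matrix is not positive definite: leading minor of order %d is not positive", k))
    }
  }
  invisible(TRUE)
}

#' Banded precision matrix and log-determinant
#'
#' For a correlation matrix induced by an `a`-banded PACF, the precision matrix
#' is itself `a`-banded, and can be computed by inverting only matrices of
#' dimension at most `a` (antedependence factorization
#' \eqn{R^{-1} = U' D^{-1} U} with `U` a unit lower-triangular band matrix of
#' one-step regression coefficients).  The log-determinant of `R` is the sum of
#' log innovation variances.
#'
#' @param p a [banded_pacf()] object, or a correlation matrix together with
#'   band `a` via the `R` argument.
#' @param R optional: supply the correlation matrix directly (skips the
#'   conversion from `p`).
#' @return list with `precision` (T x T, exactly `a`-banded) and `logdet`
#'   (\eqn{\log |R|}).
#' @export
banded_precision <- function(p, R = NULL) {
  stopifnot(inherits(p, "banded_pacf"))
  if (is.null(R)) R <- pacf_to_corr(p)
  out <- banded_precision_cpp(R, p$a)
  out
}

#' Correlation submatrix at subject-specific times
#'
#' Extracts the correlation matrix for an arbitrary increasing subset of grid
#' indices, which is how irregular per-subject measurement schedules are
#' accommodated.  The full-grid conversion result may be supplied to avoid
#' recomputation.
#'
#' @param p a [banded_pacf()] object.
#' @param times strictly increasing integer grid indices in `1..T`.
#' @param R optional precomputed full-grid correlation matrix.
#' @return correlation matrix of dimension `length(times)`.
#' @export
corr_for_times <- function(p, times, R = NULL) {
  stopifnot(inherits(p, "banded_pacf"))
  times <- as.integer(times)
  if (length(times) < 1) stop("times must be non-empty")
  if (anyDuplicated(times)) stop("times must not contain duplicates")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (min(times) < 1 || max(times) > p$T) stop("times must lie in 1..T")
  if (is.null(R)) R <- pacf_to_corr(p)
  R[times, times, drop = FALSE]
}
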