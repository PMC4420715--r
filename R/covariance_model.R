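#' Low-rank thin-plate spline basis on the time grid
#'
#' Builds the penalized-spline design used for the time-varying coefficient
#' functions of the non-stationary PACF model and (optionally) the log-variance
#' function.  For scaled time \eqn{u = t/s} the fixed design is \eqn{(1, u)}
#' and the raw radial columns are \eqn{|u - \nu_k/s|^3} at knots
#' \eqn{\nu_1 < \dots < \nu_K}.  The penalty matrix \eqn{\Omega} has entries
#' \eqn{|\nu_l/s - \nu_k/s|^3}; post-multiplying the radial columns by
#' \eqn{\Omega^{-1/2}} yields a random design whose coefficients can carry
#' independent mean-zero Normal priors with a common smoothing SD.
#'
#' @param grid_length the grid length `T`.
#' @param knots either a single integer `K` (knots placed at
#'   `s * (1:K) / K` with `s = round(0.9 * T)`, mirroring 10 knots at
#'   5, 10, ..., 50 for a grid of length 56) or an explicit strictly
#'   increasing vector of knot locations in `(0, T]`.
#' @param scale positive time scale `s`; defaults to `round(0.9 * T)` rounded
#'   to the largest knot when knots are given explicitly.
#' @return object of class `thin_plate_basis` with fields `knots`, `scale`,
#'   `X_fixed` (T x 2), `Z` (T x K reparameterized random design), `T2` (raw
#'   radial columns), `Omega`, `Omega_inv_sqrt`, `K`, `T`.
#' @export
build_thin_plate_basis <- function(grid_length, knots = 10, scale = NULL) {
  T_len <- as.integer(grid_length)
  if (T_len < 2) stop("grid_length must be at least 2")
  if (length(knots) == 1 && knots == as.integer(knots) && knots >= 1 &&
      is.null(attr(knots, "explicit"))) {
    K <- as.integer(knots)
    s_default <- max(round(0.9 * T_len), 1)
    knots <- s_default * seq_len(K) / K
  }
  knots <- as.numeric(knots)
  K <- length(knots)
  if (K < 1) stop("at least one knot is required")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (min(knots) <= 0 || max(knots) > T_len) stop("knots must lie in (0, T]")
  if (is.null(scale)) scale <- max(round(0.9 * T_len), 1)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be a positive number")

  u <- seq_len(T_len) / scale
  nu <- knots / scale
  X_fixed <- cbind(1, u)
  colnames(X_fixed) <- c("intercept", "linear")
  T2 <- abs(outer(u, nu, "-"))^3
  Omega <- abs(outer(nu, nu, "-"))^3

  eg <- eigen(Omega, symmetric = TRUE)
  ev <- eg$values
  if (any(abs(ev) < 1e-10)) {
    stop("penalty matrix Omega is numerically singular; jitter the knots")
  }
  # Omega is indefinite in general; |Omega|^{-1/2} on the eigenvalue magnitudes
  # keeps the reparameterized design real while reproducing T2 Omega^{-1} T2'
  # up to eigenvalue signs.  For thin-plate radial bases on distinct knots the
  # standard construction uses the symmetric square root of Omega itself.
  Omega_inv_sqrt <- eg$vectors %*% diag(1 / sqrt(abs(ev)), K) %*% t(eg$vectors)
  sgn <- eg$vectors %*% diag(sign(ev), K) %*% t(eg$vectors)
  Z <- T2 %*% Omega_inv_sqrt
  structure(list(knots = knots, scale = scale, X_fixed = X_fixed, Z = Z,
                 T2 = T2, Omega = Omega, Omega_inv_sqrt = Omega_inv_sqrt,
                 sign_matrix = sgn, K = K, T = T_len),
            class = "thin_plate_basis")
}

#' @export
print.thin_plate_basis <- function(x, ...) {
  cat(sprintf("thin_plate_basis: T = %d, K = %d knots, scale = %g\n",
              x$T, x$K, x$scale))
  invisible(x)
}

#' Covariance model parameters
#'
#' Bundles the parameters of the banded PACF covariance models.  The
#' `stationary` family uses scalars `gamma0`, `gamma1` (and optionally
#' `gamma2` for a quadratic lag term): on the Fisher-z scale,
#' \eqn{z(\pi(t,t+j)) = \gamma_0 + \gamma_1 j} for \eqn{j \le a}.  The
#' `nonstationary` family replaces the scalars with smooth functions of time,
#' \eqn{g_{t0}} and \eqn{g_{t1}}, each represented by two fixed-effect
#' coefficients (intercept, linear) plus `K` spline random coefficients on the
#' reparameterized thin-plate basis.  The marginal variance is log-linear:
#' \eqn{\sigma^2(t) = \exp(\alpha_0 + \alpha_1 t / s_{var})}.  A random
#' intercept SD `sigma_b` adds non-diminishing correlation.
#'
#' @param family `"stationary"` or `"nonstationary"`.
#' @param a band width.
#' @param gamma stationary: numeric of length 2 (or 3 with quadratic lag),
#'   `gamma[2] <= 0` enforced (monotone non-increasing decay).
#' @param g0_fixed,g0_xi,g1_fixed,g1_xi non-stationary blocks: fixed pairs and
#'   spline coefficients for \eqn{g_{t0}} and \eqn{g_{t1}}.
#' @param alpha numeric length 2, log-variance intercept and slope.
#' @param sigma_b random-intercept SD, `>= 0`.
#' @param sigma_g0,sigma_g1 smoothing SDs for the spline blocks (priors of the
#'   random coefficients), `>= 0`.
#' @param var_scale time scale for the variance model (defaults to the grid
#'   length at evaluation time when `NULL`).
#' @return object of class `cov_params`.
#' @export
cov_params <- function(family = c("stationary", "nonstationary"), a,
                       gamma = NULL, g0_fixed = NULL, g0_xi = NULL,
                       g1_fixed = NULL, g1_xi = NULL,
                       alpha = c(0, 0), sigma_b = 0,
                       sigma_g0 = 1, sigma_g1 = 1, var_scale = NULL) {
  family <- match.arg(family)
  a <- as.integer(a)
  if (a < 0) stop("band width a must be non-negative")
  if (sigma_b < 0) stop("sigma_b must be non-negative")
  if (length(alpha) != 2) stop("alpha must have length 2 (log-linear variance)")
  if (family == "stationary") {
    if (is.null(gamma) || !length(gamma) %in% c(2L, 3L)) {
      stop("stationary family requires gamma of length 2 (or 3 with quadratic lag)")
    }
    if (gamma[2] > 0) stop("stationary slope gamma1 must be <= 0 (non-increasing decay)")
  } else {
    if (is.null(g0_fixed) || is.null(g0_xi) || is.null(g1_fixed) || is.null(g1_xi)) {
      stop("nonstationary family requires g0_fixed, g0_xi, g1_fixed, g1_xi")
    }
    if (length(g0_fixed) != 2 || length(g1_fixed) != 2) {
      stop("fixed-effect blocks must have length 2 (intercept, linear)")
    }
    if (sigma_g0 < 0 || sigma_g1 < 0) stop("smoothing SDs must be non-negative")
  }
  structure(list(family = family, a = a, gamma = gamma,
                 g0_fixed = g0_fixed, g0_xi = g0_xi,
                 g1_fixed = g1_fixed, g1_xi = g1_xi,
                 alpha = as.numeric(alpha), sigma_b = sigma_b,
                 sigma_g0 = sigma_g0, sigma_g1 = sigma_g1,
                 var_scale = var_scale),
            class = "cov_params")
}

# time-varying coefficient functions over the grid (nonstationary family)
.g_functions <- function(params, basis) {
  g0 <- drop(basis$X_fixed %*% params$g0_fixed + basis$Z %*% params$g0_xi)
  g1 <- drop(basis$X_fixed %*% params$g1_fixed + basis$Z %*% params$g1_xi)
  list(g0 = g0, g1 = g1)
}

#' Evaluate the PACF model
#'
#' Maps covariance parameters to a [banded_pacf()] object on the grid.
#' Stationary family: \eqn{z(\pi(t,t+j)) = \gamma_0 + \gamma_1 j}
#' (plus \eqn{\gamma_2 j^2} if a quadratic term is present) for \eqn{j \le a}.
#' Non-stationary: \eqn{z(\pi(t,t+j)) = g_{t0} + g_{t1} j}, indexed by the
#' left endpoint `t`.  The constraint \eqn{g_{t1} \le 0} at every grid point is
#' checked and violations raise an error (samplers reject such proposals
#' rather than clamping).
#'
#' @param params a [cov_params()] object.
#' @param grid_length grid length `T` (stationary family).
#' @param basis a [build_thin_plate_basis()] object (non-stationary family;
#'   supplies `T`).
#' @return a [banded_pacf()] object.
#' @export
evaluate_pacf <- function(params, grid_length = NULL, basis = NULL) {
  stopifnot(inherits(params, "cov_params"))
  if (params$family == "stationary") {
    if (is.null(grid_length)) {
      if (is.null(basis)) stop("grid_length required for the stationary family")
      grid_length <- basis$T
    }
    T_len <- as.integer(grid_length)
    a <- min(params$a, T_len - 1L)
    pim <- diag(T_len)
    if (a >= 1) {
      for (j in seq_len(a)) {
        zj <- params$gamma[1] + params$gamma[2] * j
        if (length(params$gamma) == 3) zj <- zj + params$gamma[3] * j^2
        v <- tanh(zj)
        if (abs(v) >= 1 - 1e-12) stop("PACF model evaluates outside (-1, 1)")
        idx <- seq_len(T_len - j)
        pim[cbind(idx, idx + j)] <- v
        pim[cbind(idx + j, idx)] <- v
      }
    }
    return(banded_pacf(pim, a))
  }
  if (is.null(basis)) stop("nonstationary family requires a thin_plate_basis")
  T_len <- basis$T
  a <- min(params$a, T_len - 1L)
  g <- .g_functions(params, basis)
  if (any(g$g1 > 0)) {
    stop("constraint violated: g_t1 > 0 at some grid point (decay must be non-increasing)")
  }
  pim <- diag(T_len)
  if (a >= 1) {
    for (j in seq_len(a)) {
      idx <- seq_len(T_len - j)
      v <- tanh(g$g0[idx] + g$g1[idx] * j)
      if (any(abs(v) >= 1 - 1e-12)) stop("PACF model evaluates outside (-1, 1)")
      pim[cbind(idx, idx + j)] <- v
      pim[cbind(idx + j, idx)] <- v
    }
  }
  banded_pacf(pim, a)
}

#' Evaluate the marginal variance function
#'
#' Log-linear variance model \eqn{\sigma^2(t) = \exp(\alpha_0 + \alpha_1
#' t/s_{var})}.  The time scaling `s_var` keeps the slope O(1); it defaults to
#' the grid length.
#'
#' @param params a [cov_params()] object.
#' @param t grid index vector.
#' @param grid_length grid length, used for the default variance time scale.
#' @return positive variances, one per element of `t`.
#' @export
evaluate_variance <- function(params, t, grid_length = max(t)) {
  stopifnot(inherits(params, "cov_params"))
  s_var <- if (is.null(params$var_scale)) grid_length else params$var_scale
  exp(params$alpha[1] + params$alpha[2] * t / s_var)
}

#' Subject-level marginal covariance matrix
#'
#' Assembles \eqn{\Sigma_i = \sigma_b^2 J + S_i R_i S_i} at the subject's
#' measurement times: random-intercept component (all-ones matrix `J`) plus
#' the serial component with marginal SDs `S_i` and PACF-induced correlations
#' `R_i`.
#'
#' @param params a [cov_params()] object.
#' @param times increasing grid indices.
#' @param grid_length grid length `T`.
#' @param basis thin-plate basis (non-stationary family).
#' @param R optional precomputed full-grid correlation matrix.
#' @return covariance matrix of dimension `length(times)`.
#' @export
build_subject_covariance <- function(params, times, grid_length = NULL,
                                     basis = NULL, R = NULL) {
  if (is.null(grid_length)) grid_length <- if (!is.null(basis)) basis$T else max(times)
  p <- evaluate_pacf(params, grid_length = grid_length, basis = basis)
  if (is.null(R)) R <- pacf_to_corr(p)
  Rsub <- R[times, times, drop = FALSE]
  sds <- sqrt(evaluate_variance(params, times, grid_length = grid_length))
  params$sigma_b^2 + outer(sds, sds) * Rsub
}
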