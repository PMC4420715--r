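#' Conditional linear model parameters
#'
#' In the conditional linear model (CLM) for informative dropout, the mean
#' regression coefficients are linear functions of each subject's observed
#' dropout time `d`: \eqn{\beta_k(d) = \theta_{k0} + \theta_{k1} d^*}, with
#' \eqn{d^* = (d - \bar d)/s_d} a centered, rescaled dropout time.  Averaging
#' \eqn{\beta_k(d)} over the dropout distribution recovers marginal covariate
#' effects (see [marginal_effects()]).
#'
#' @param theta numeric length 8, ordered
#'   `(theta00, theta01, theta10, theta11, theta20, theta21, theta30, theta31)`:
#'   intercept, time slope (per year), dose effect and dose-by-time
#'   interaction, each with its dropout-time modifier.
#' @param dropout_center \eqn{\bar d}, usually the sample mean of the observed
#'   dropout times (in the units dropout is recorded in, e.g. weeks).
#' @param dropout_scale positive rescaling `s_d` of the centered dropout time
#'   (default 100 for dropout in weeks over a multi-year study).
#' @param time_scale grid units per time unit of the slope; default 13
#'   (4-week grid, slope per year).
#' @return object of class `clm_params`.
#' @export
clm_params <- function(theta, dropout_center, dropout_scale = 100,
                       time_scale = 13) {
  theta <- as.numeric(theta)
  if (length(theta) != 8) stop("theta must have length 8")
  if (!is.numeric(dropout_scale) || dropout_scale <= 0) {
    stop("dropout_scale must be positive")
  }
  names(theta) <- c("theta00", "theta01", "theta10", "theta11",
                    "theta20", "theta21", "theta30", "theta31")
  structure(list(theta = theta, dropout_center = dropout_center,
                 dropout_scale = dropout_scale, time_scale = time_scale),
            class = "clm_params")
}

#' Dropout-conditional regression coefficients
#'
#' @param params a [clm_params()] object.
#' @param d observed dropout time(s), same units as `dropout_center`.
#' @return matrix with one row per element of `d` and columns
#'   `beta0..beta3` (intercept, slope, dose, dose-by-slope).
#' @export
clm_coefficients <- function(params, d) {
  stopifnot(inherits(params, "clm_params"))
  if (any(d <= 0)) stop("dropout times must be positive")
  dstar <- (d - params$dropout_center) / params$dropout_scale
  th <- params$theta
  cbind(beta0 = th[1] + th[2] * dstar,
        beta1 = th[3] + th[4] * dstar,
        beta2 = th[5] + th[6] * dstar,
        beta3 = th[7] + th[8] * dstar)
}

#' CLM mean vector for one subject
#'
#' \eqn{\mu(t) = \beta_0(d) + \beta_1(d)(t-1)/s_t + \beta_2(d)\,dose +
#' \beta_3(d)\,dose\,(t-1)/s_t}; grid index `t = 1` is enrollment, and the
#' time scaling `s_t` (default 13) makes \eqn{\beta_1} a per-year rate on a
#' 4-week grid.  The random intercept is part of the covariance, not the mean.
#'
#' @param params a [clm_params()] object.
#' @param times grid indices.
#' @param dose 0/1 treatment indicator.
#' @param d observed dropout time.
#' @return numeric mean vector, one element per time.
#' @export
clm_mean_vector <- function(params, times, dose, d) {
  b <- clm_coefficients(params, d)
  u <- (times - 1) / params$time_scale
  drop(b[1, "beta0"] + b[1, "beta1"] * u + b[1, "beta2"] * dose +
         b[1, "beta3"] * dose * u)
}

#' Linear mixed model (comparator) parameters
#'
#' Random-intercept/random-slope LMM whose random-effect covariance `G` is
#' parameterized through the modified Cholesky decomposition: the slope is
#' regressed on the intercept, \eqn{b_1 = \lambda b_0 + e}, so
#' \eqn{G = [\sigma_0^2, \lambda \sigma_0^2; \lambda \sigma_0^2,
#' \lambda^2 \sigma_0^2 + \sigma_e^2]} is positive definite whenever
#' \eqn{\sigma_0, \sigma_e > 0}.  Residuals are independent Gaussian with SD
#' `sigma_eps`.
#'
#' @param lambda regression coefficient of the slope on the intercept.
#' @param sigma0 intercept SD.
#' @param sigma_e innovation SD of the slope.
#' @param sigma_eps residual SD.
#' @param time_scale grid units per slope time unit (default 13).
#' @return object of class `lmm_params`.
#' @export
lmm_params <- function(lambda, sigma0, sigma_e, sigma_eps, time_scale = 13) {
  if (sigma0 <= 0 || sigma_e <= 0 || sigma_eps <= 0) {
    stop("sigma0, sigma_e and sigma_eps must be positive")
  }
  structure(list(lambda = lambda, sigma0 = sigma0, sigma_e = sigma_e,
                 sigma_eps = sigma_eps, time_scale = time_scale),
            class = "lmm_params")
}

#' Random-effects covariance implied by the modified Cholesky parameters
#'
#' @param params an [lmm_params()] object.
#' @return 2 x 2 matrix `G` with entries \eqn{\sigma_0^2},
#'   \eqn{\sigma_{01} = \lambda \sigma_0^2},
#'   \eqn{\sigma_1^2 = \lambda^2 \sigma_0^2 + \sigma_e^2}.
#' @export
lmm_G <- function(params) {
  stopifnot(inherits(params, "lmm_params"))
  s0sq <- params$sigma0^2
  matrix(c(s0sq, params$lambda * s0sq,
           params$lambda * s0sq, params$lambda^2 * s0sq + params$sigma_e^2),
         2, 2)
}

#' Marginal covariance of the LMM comparator
#'
#' \eqn{\Sigma(t, t') = z_t' G z_{t'} + \sigma_\epsilon^2 1\{t = t'\}} with
#' \eqn{z_t = (1, (t-1)/s_t)'}; random effects integrated out.
#'
#' @param params an [lmm_params()] object.
#' @param times grid indices.
#' @return covariance matrix of dimension `length(times)`.
#' @export
lmm_marginal_covariance <- function(params, times) {
  stopifnot(inherits(params, "lmm_params"))
  u <- (times - 1) / params$time_scale
  Zt <- cbind(1, u)
  Zt %*% lmm_G(params) %*% t(Zt) + diag(params$sigma_eps^2, length(times))
}
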