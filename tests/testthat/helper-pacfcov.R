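# shared fixtures: random banded PACFs and independent oracles

# random banded partial autocorrelation matrix (values kept away from +-1)
rand_banded_pacf <- function(T_len, a, lim = 0.8) {
  pim <- diag(T_len)
  for (j in seq_len(a)) {
    for (t in seq_len(T_len - j)) {
      v <- stats::runif(1, -lim, lim)
      pim[t, t + j] <- v
      pim[t + j, t] <- v
    }
  }
  banded_pacf(pim, a)
}

# independent oracle: partial correlation of Y_t and Y_{t+j} given the
# intervening values, via the precision matrix of the block (t, ..., t+j)
pcor_oracle <- function(R, t, j) {
  idx <- t:(t + j)
  P <- solve(R[idx, idx])
  -P[1, j + 1] / sqrt(P[1, 1] * P[j + 1, j + 1])
}

# dense R-level PACF -> correlation conversion (independent of the C++ path):
# builds the joint covariance sequentially from the regression-residual
# characterization, one lag at a time, using plain base-R solves
dense_pacf_to_corr_oracle <- function(p) {
  T_len <- p$T
  R <- diag(T_len)
  for (j in seq_len(T_len - 1)) {
    for (t in seq_len(T_len - j)) {
      if (j == 1) {
        R[t, t + 1] <- R[t + 1, t] <- p$pi[t, t + 1]
      } else {
        mid <- (t + 1):(t + j - 1)
        Rm <- R[mid, mid, drop = FALSE]
        r1 <- R[t, mid]
        r3 <- R[t + j, mid]
        d1 <- 1 - drop(r1 %*% solve(Rm, r1))
        d3 <- 1 - drop(r3 %*% solve(Rm, r3))
        rho <- drop(r1 %*% solve(Rm, r3)) +
          p$pi[t, t + j] * sqrt(max(d1, 0) * max(d3, 0))
        R[t, t + j] <- R[t + j, t] <- rho
      }
    }
  }
  R
}

# dense multivariate normal log density (oracle for the likelihood kernels)
dmvnorm_log_oracle <- function(y, mu, S) {
  n <- length(y)
  ld <- determinant(S, logarithm = TRUE)$modulus[1]
  r <- y - mu
  -0.5 * (n * log(2 * pi) + ld + drop(r %*% solve(S, r)))
}

# small stationary CLM scenario used by several fitting tests
small_scenario <- function(N = 60, T = 10, seed = 1) {
  sim_scenario(
    N = N, T = T,
    cov = cov_params("stationary", a = 2, gamma = c(1.2, -0.25),
                     alpha = c(4.65, -1.76), sigma_b = 8),
    mean = clm_params(c(30.4, 13.1, -4.8, 7.4, -1.6, 2.2, 1.0, -2.2),
                      dropout_center = 50),
    gap_probs = c(0.5, 0.3, 0.2),
    dropout = list(type = "categorical",
                   values = seq(8, T * 4, by = 4),
                   probs = rep(1, length(seq(8, T * 4, by = 4)))),
    dose_prob = 0.5, resolution = 4, seed = seed)
}

# named truth vector matching the stationary-recovery benchmark scenario
stationary_truth <- function() {
  c(theta00 = 30.4, theta01 = 13.1, theta10 = -4.8, theta11 = 7.4,
    theta20 = -1.6, theta21 = 2.2, theta30 = 1.0, theta31 = -2.2,
    gamma0 = 1.2, gamma1 = -0.25, alpha0 = 4.65, alpha1 = -1.76, sigma_b = 8)
}
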