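test_that("thin-plate basis reproduces the reference layout (K=10, scale 50)", {
  b <- build_thin_plate_basis(56, knots = 10, scale = 50)
  expect_equal(b$knots, seq(5, 50, by = 5))
  expect_equal(dim(b$X_fixed), c(56L, 2L))
  expect_equal(dim(b$Z), c(56L, 10L))
  expect_equal(diag(b$Omega), rep(0, 10))
  expect_equal(b$Omega, t(b$Omega))
})

test_that("reparameterized random design carries the thin-plate penalty", {
  b <- build_thin_plate_basis(30, knots = 8)
  # the penalty matrix has zero trace, hence mixed-sign eigenvalues; the
  # magnitude-root reparameterization satisfies the exact sign-corrected
  # identity Z sgn Z' = T2 Omega^{-1} T2'
  lhs <- b$Z %*% b$sign_matrix %*% t(b$Z)
  rhs <- b$T2 %*% solve(b$Omega) %*% t(b$T2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # and |Omega| is reproduced: (Z' Z) has the |eigenvalue|-whitened geometry
  M <- b$Omega_inv_sqrt %*% b$Omega %*% b$Omega_inv_sqrt
  expect_equal(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               rep(1, b$K), tolerance = 1e-8)
  expect_error(build_thin_plate_basis(30, knots = c(5, 5, 10)), "increasing")
  expect_error(build_thin_plate_basis(30, knots = c(5, 10, 40)), "\\(0, T\\]")
})

test_that("evaluate_pacf implements the z-linear lag model with banding", {
  cp <- cov_params("stationary", a = 2, gamma = c(1, -0.5))
  p <- evaluate_pacf(cp, grid_length = 10)
  expect_equal(p$pi[1, 2], tanh(0.5), tolerance = 1e-12)   # j=1: z = 1 - 0.5
  expect_equal(p$pi[1, 3], tanh(0))                         # j=2
  expect_equal(p$pi[1, 4], 0)                               # j=3 beyond band
  expect_equal(p$pi[3, 4], p$pi[7, 8])                      # stationarity

  cp0 <- cov_params("stationary", a = 3, gamma = c(0, 0))
  expect_equal(pacf_to_corr(evaluate_pacf(cp0, grid_length = 6)), diag(6))

  expect_error(cov_params("stationary", a = 2, gamma = c(1, 0.2)),
               "gamma1 must be <= 0")
})

test_that("non-stationary family reduces to stationary and enforces g_t1 <= 0", {
  T_len <- 15
  b <- build_thin_plate_basis(T_len, knots = 6)
  ns <- cov_params("nonstationary", a = 2,
                   g0_fixed = c(1, 0), g0_xi = rep(0, 6),
                   g1_fixed = c(-0.5, 0), g1_xi = rep(0, 6))
  st <- cov_params("stationary", a = 2, gamma = c(1, -0.5))
  expect_equal(evaluate_pacf(ns, basis = b)$pi,
               evaluate_pacf(st, grid_length = T_len)$pi, tolerance = 1e-12)

  bad <- cov_params("nonstationary", a = 2,
                    g0_fixed = c(1, 0), g0_xi = rep(0, 6),
                    g1_fixed = c(0.2, 0), g1_xi = rep(0, 6))
  expect_error(evaluate_pacf(bad, basis = b), "g_t1 > 0")
})

test_that("in-band partials decay in lag when g_t1 <= 0", {
  # with g_t1 <= 0 the z-scale predictor decreases linearly in lag, so the
  # signed partials are non-increasing; their absolute values are
  # non-increasing as long as the predictor stays non-negative (|tanh| turns
  # around once the predictor crosses zero, so the absolute statement needs
  # g_t0 + a g_t1 >= 0)
  T_len <- 12
  b <- build_thin_plate_basis(T_len, knots = 5)
  set.seed(411)
  for (rep in 1:5) {
    g0 <- runif(1, 0.8, 2)
    g1 <- -runif(1, 0.05, g0 / 4)            # keeps g0 + 4 g1 >= 0
    ns <- cov_params("nonstationary", a = 4,
                     g0_fixed = c(g0, 0), g0_xi = rep(0, 5),
                     g1_fixed = c(g1, 0), g1_xi = rep(0, 5),
                     sigma_b = 0)
    p <- evaluate_pacf(ns, basis = b)
    for (t in 1:(T_len - 4)) {
      vals <- sapply(1:4, function(j) p$pi[t, t + j])
      expect_true(all(diff(vals) <= 1e-12))        # signed monotonicity
      expect_true(all(diff(abs(vals)) <= 1e-12))   # absolute, since z >= 0
    }
  }
  # signed monotonicity holds even when the predictor changes sign
  ns2 <- cov_params("nonstationary", a = 4,
                    g0_fixed = c(0.5, 0), g0_xi = rep(0, 5),
                    g1_fixed = c(-0.6, 0), g1_xi = rep(0, 5))
  p2 <- evaluate_pacf(ns2, basis = b)
  vals <- sapply(1:4, function(j) p2$pi[1, 1 + j])
  expect_true(all(diff(vals) < 0))
})

test_that("log-linear variance function is positive and monotone", {
  cp <- cov_params("stationary", a = 1, gamma = c(0, 0), alpha = c(0, 0))
  expect_equal(evaluate_variance(cp, 1:10, grid_length = 10), rep(1, 10))

  cp2 <- cov_params("stationary", a = 1, gamma = c(0, 0), alpha = c(4.65, -1.76),
                    var_scale = 56)
  v <- evaluate_variance(cp2, 1:56, grid_length = 56)
  expect_true(all(diff(v) < 0))
  expect_gt(v[56], 0)
  expect_gt(v[1], v[56])
  expect_equal(v[56], exp(4.65 - 1.76), tolerance = 1e-12)
})

test_that("subject covariance assembles sigma_b^2 J + S R S", {
  cp <- cov_params("stationary", a = 1, gamma = c(0, 0), alpha = c(0, 0),
                   sigma_b = 2)
  S <- build_subject_covariance(cp, times = c(2, 5), grid_length = 8)
  expect_equal(S, matrix(c(5, 4, 4, 5), 2, 2))

  cp0 <- cov_params("stationary", a = 1, gamma = c(0.5, -0.2),
                    alpha = c(1, -0.5), sigma_b = 0)
  S1 <- build_subject_covariance(cp0, times = 3, grid_length = 8)
  expect_equal(drop(S1), evaluate_variance(cp0, 3, grid_length = 8))

  set.seed(412)
  min_eig <- Inf
  for (rep in 1:100) {
    cp <- cov_params("stationary", a = 2,
                     gamma = c(runif(1, -1, 1.5), -runif(1, 0, 0.8)),
                     alpha = runif(2, -1, 1), sigma_b = runif(1, 0, 5))
    times <- sort(sample(1:20, 8))
    S <- build_subject_covariance(cp, times, grid_length = 20)
    min_eig <- min(min_eig, min(eigen(S, symmetric = TRUE,
                                      only.values = TRUE)$values))
  }
  expect_gt(min_eig, 0)
})

test_that("banding holds for the serial precision, not the full covariance", {
  set.seed(413)
  p <- rand_banded_pacf(12, 2)
  Rinv <- banded_precision(p)$precision
  off <- abs(row(Rinv) - col(Rinv)) > 2
  expect_lt(max(abs(Rinv[off])), 1e-12)

  cp <- cov_params("stationary", a = 2, gamma = c(1, -0.4), alpha = c(0, 0),
                   sigma_b = 2)
  Sigma <- build_subject_covariance(cp, times = 1:12, grid_length = 12)
  Sinv <- solve(Sigma)
  off3 <- abs(row(Sinv) - col(Sinv)) > 2
  expect_gt(max(abs(Sinv[off3])), 1e-6)   # random intercept destroys banding
})
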