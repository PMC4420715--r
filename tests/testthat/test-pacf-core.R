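test_that("Fisher z-transform and its inverse behave as a link function", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(c(-0.3, 0.7)), atanh(c(-0.3, 0.7)))
  expect_equal(inverse_fisher_z(fisher_z(0.9)), 0.9)
  expect_equal(inverse_fisher_z(fisher_z(-0.99)), -0.99)
  expect_error(fisher_z(1), "\\(-1, 1\\)")
  expect_error(fisher_z(-1.2), "\\(-1, 1\\)")
})

test_that("banded_pacf validates its domain", {
  pim <- diag(4)
  pim[1, 2] <- pim[2, 1] <- 0.5
  expect_s3_class(banded_pacf(pim, 1), "banded_pacf")
  expect_error(banded_pacf(pim, 0), "exactly zero")       # value outside band
  pim2 <- pim
  pim2[1, 2] <- pim2[2, 1] <- 1 - 1e-13                    # too close to 1
  expect_error(banded_pacf(pim2, 1), "strictly inside")
  expect_error(banded_pacf(pim, 4), "band width")
  pim3 <- pim
  pim3[1, 2] <- 0.4                                        # asymmetric
  expect_error(banded_pacf(pim3, 1), "symmetric")
})

test_that("pacf_to_corr reproduces hand-checked low-dimensional cases", {
  # no correlation
  p0 <- banded_pacf(diag(5), 2)
  expect_equal(pacf_to_corr(p0), diag(5))

  # T=3: rho(1,3) = 0.5*0.5 + 0.2*sqrt(0.75*0.75) = 0.40
  pim <- diag(3)
  pim[1, 2] <- pim[2, 1] <- 0.5
  pim[2, 3] <- pim[3, 2] <- 0.5
  pim[1, 3] <- pim[3, 1] <- 0.2
  R <- pacf_to_corr(banded_pacf(pim, 2))
  expect_equal(R[1, 3], 0.40)
  # oracle: partial correlation from the precision of the (1,2,3) block
  expect_equal(pcor_oracle(R, 1, 2), 0.2, tolerance = 1e-12)
})

test_that("a = 1 with constant lag-1 partials is exactly AR(1)", {
  for (phi in c(-0.3, 0.6, 0.9)) {
    T_len <- 8
    pim <- diag(T_len)
    for (t in seq_len(T_len - 1)) pim[t, t + 1] <- pim[t + 1, t] <- phi
    R <- pacf_to_corr(banded_pacf(pim, 1))
    expect_equal(R, phi^abs(outer(1:T_len, 1:T_len, "-")), tolerance = 1e-12)
    # monotone decay of |rho| in lag
    lags <- sapply(1:(T_len - 1), function(j) abs(R[1, 1 + j]))
    expect_true(all(diff(lags) < 0))
  }
})

test_that("pacf_to_corr matches the regression-residual oracle on random draws", {
  set.seed(401)
  for (rep in 1:10) {
    T_len <- sample(5:12, 1)
    a <- sample(1:3, 1)
    p <- rand_banded_pacf(T_len, a)
    R <- pacf_to_corr(p)
    expect_equal(R, dense_pacf_to_corr_oracle(p), tolerance = 1e-12)
    # in-band partials recovered by the precision-based oracle, zero beyond
    for (t in sample(seq_len(T_len - 1), 2)) {
      for (j in seq_len(min(a + 2, T_len - t))) {
        expect_equal(pcor_oracle(R, t, j), p$pi[t, t + j], tolerance = 1e-10)
      }
    }
  }
})

test_that("corr_to_pacf inverts pacf_to_corr and handles textbook cases", {
  expect_equal(corr_to_pacf(diag(4), 2)$pi, diag(4))
  Req <- matrix(0.5, 3, 3); diag(Req) <- 1
  expect_equal(corr_to_pacf(Req, 2)$pi[1, 3], 1 / 3, tolerance = 1e-12)

  set.seed(402)
  worst <- 0
  for (rep in 1:50) {
    p <- rand_banded_pacf(10, 3)
    p2 <- corr_to_pacf(pacf_to_corr(p), 3)
    worst <- max(worst, max(abs(p2$pi - p$pi)))
  }
  expect_lt(worst, 1e-10)

  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(corr_to_pacf(bad, 1), "leading minor of order 2")
})

test_that("banded_precision matches dense inversion with exact banding", {
  # identity
  bp0 <- banded_precision(banded_pacf(diag(6), 2))
  expect_equal(bp0$precision, diag(6))
  expect_equal(bp0$logdet, 0)

  # AR(1) tridiagonal
  pim <- diag(4)
  for (t in 1:3) pim[t, t + 1] <- pim[t + 1, t] <- 0.6
  p <- banded_pacf(pim, 1)
  R <- pacf_to_corr(p)
  bp <- banded_precision(p)
  expect_equal(bp$precision, solve(R), tolerance = 1e-10)

  set.seed(403)
  p <- rand_banded_pacf(20, 3)
  R <- pacf_to_corr(p)
  bp <- banded_precision(p)
  expect_equal(bp$precision, solve(R), tolerance = 1e-8)
  expect_equal(bp$logdet, determinant(R, logarithm = TRUE)$modulus[1],
               tolerance = 1e-8, ignore_attr = TRUE)
  off <- abs(row(R) - col(R)) > 3
  expect_lt(max(abs(bp$precision[off])), 1e-12)
})

test_that("corr_for_times extracts subject submatrices", {
  set.seed(404)
  p <- rand_banded_pacf(8, 2)
  R <- pacf_to_corr(p)
  expect_equal(corr_for_times(p, 1:8), R)
  expect_equal(corr_for_times(p, 5), matrix(1, 1, 1))
  expect_equal(corr_for_times(p, c(1, 3, 7)), R[c(1, 3, 7), c(1, 3, 7)])
  expect_error(corr_for_times(p, c(3, 3)), "duplicates")
  expect_error(corr_for_times(p, c(7, 3)), "increasing")
  expect_error(corr_for_times(p, c(1, 9)), "1..T")
})

test_that("positive definiteness holds across random banded draws", {
  set.seed(405)
  min_eig <- Inf
  for (rep in 1:40) {
    T_len <- sample(5:25, 1)
    a <- sample(1:5, 1)
    p <- rand_banded_pacf(T_len, min(a, T_len - 1))
    ev <- eigen(pacf_to_corr(p), symmetric = TRUE, only.values = TRUE)$values
    min_eig <- min(min_eig, min(ev))
  }
  expect_gt(min_eig, 0)
})
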