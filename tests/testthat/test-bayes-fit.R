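make_params <- function(theta, gamma = c(1, -0.4), alpha = c(0, 0), sigma_b = 0) {
  c(theta, gamma0 = unname(gamma[1]), gamma1 = unname(gamma[2]),
    alpha0 = unname(alpha[1]), alpha1 = unname(alpha[2]), sigma_b = sigma_b)
}

simple_theta <- function(b0 = 0, b1 = 0, b2 = 0, b3 = 0) {
  c(beta0 = b0, beta1 = b1, beta2 = b2, beta3 = b3)
}

test_that("log_marginal_likelihood reduces to the standard normal density", {
  dat <- long_data(data.frame(id = 1, time = 1, gridtime = 1, y = 0,
                              dose = 0, dropout = 1), T = 1, resolution = 1)
  model <- pacf_model("stationary", a = 2, mean = "simple")
  ll <- log_marginal_likelihood(dat, make_params(simple_theta()), model)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("log-likelihood is additive over disjoint subject sets", {
  set.seed(431)
  datA <- simulate_dataset(small_scenario(N = 8, T = 8), seed = 21)
  datB <- simulate_dataset(small_scenario(N = 5, T = 8), seed = 22)
  dfB <- as.data.frame(datB)
  dfB$id <- dfB$id + 100
  datAB <- long_data(rbind(as.data.frame(datA), dfB), T = 8, resolution = 4)
  model <- pacf_model("stationary", a = 2, mean = "simple")
  pars <- make_params(simple_theta(25, -3, 1, 0.5), gamma = c(1, -0.3),
                      alpha = c(3, -1), sigma_b = 5)
  expect_equal(log_marginal_likelihood(datAB, pars, model),
               log_marginal_likelihood(datA, pars, model) +
                 log_marginal_likelihood(datB, pars, model),
               tolerance = 1e-10)
})

test_that("banded likelihood equals the dense MVN oracle", {
  set.seed(432)
  for (rep in 1:5) {
    dat <- simulate_dataset(small_scenario(N = 5, T = 10), seed = 500 + rep)
    model <- pacf_model("stationary", a = 2, mean = "simple")
    pars <- make_params(simple_theta(runif(1, 20, 30), runif(1, -5, 0),
                                     runif(1, -2, 2), runif(1, -1, 1)),
                        gamma = c(runif(1, 0, 1.5), -runif(1, 0, 0.6)),
                        alpha = c(runif(1, 2, 4), -runif(1, 0, 2)),
                        sigma_b = runif(1, 0, 6))
    ll <- log_marginal_likelihood(dat, pars, model)

    # oracle: dense per-subject MVN density from first principles
    pim <- diag(10)
    for (j in 1:2) for (t in 1:(10 - j)) {
      v <- tanh(pars[["gamma0"]] + pars[["gamma1"]] * j)
      pim[t, t + j] <- pim[t + j, t] <- v
    }
    Rd <- dense_pacf_to_corr_oracle(banded_pacf(pim, 2))
    sds <- sqrt(exp(pars[["alpha0"]] + pars[["alpha1"]] * (1:10) / 10))
    ll_oracle <- 0
    for (i in unique(dat$id)) {
      sub <- dat[dat$id == i, ]
      tt <- sub$gridtime
      u <- (tt - 1) / 13
      mu <- pars[["beta0"]] + pars[["beta1"]] * u + pars[["beta2"]] * sub$dose +
        pars[["beta3"]] * sub$dose * u
      S <- pars[["sigma_b"]]^2 + outer(sds[tt], sds[tt]) * Rd[tt, tt]
      ll_oracle <- ll_oracle + dmvnorm_log_oracle(sub$y, mu, S)
    }
    expect_equal(ll, ll_oracle, tolerance = 1e-8)
  }
})

test_that("run_mcmc is deterministic and honors iterations = 0", {
  dat <- simulate_dataset(small_scenario(N = 30, T = 8), seed = 3)
  model <- pacf_model("stationary", a = 2, mean = "clm")
  f1 <- run_mcmc(dat, model, iterations = 40, burn_in = 20, chains = 2, seed = 9)
  f2 <- run_mcmc(dat, model, iterations = 40, burn_in = 20, chains = 2, seed = 9)
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(f1$chains[[2]]$draws, f2$chains[[2]]$draws)
  f3 <- run_mcmc(dat, model, iterations = 40, burn_in = 20, chains = 1, seed = 10)
  expect_false(identical(f1$chains[[1]]$draws, f3$chains[[1]]$draws))

  f0 <- run_mcmc(dat, model, iterations = 0, chains = 1, seed = 9)
  expect_equal(nrow(f0$chains[[1]]$draws), 1L)
  expect_named(f0$chains[[1]]$draws[1, ], f0$param_names)
})

test_that("adapted acceptance rates land in the workable range", {
  dat <- simulate_dataset(small_scenario(N = 80, T = 10), seed = 4)
  model <- pacf_model("stationary", a = 2, mean = "clm")
  fit <- run_mcmc(dat, model, iterations = 400, burn_in = 300, chains = 1,
                  seed = 12)
  rates <- fit$acceptance[[1]]
  expect_true(all(rates >= 0.15 & rates <= 0.5))
})

test_that("DIC satisfies its identities", {
  dat <- simulate_dataset(small_scenario(N = 40, T = 8), seed = 6)
  model <- pacf_model("stationary", a = 2, mean = "clm")
  fit <- run_mcmc(dat, model, iterations = 150, burn_in = 100, chains = 2,
                  seed = 13)
  dic <- compute_dic(fit, dat)
  expect_equal(dic$DIC, dic$Dbar + dic$pD)
  expect_equal(dic$pD, dic$Dbar - dic$Dhat)
  expect_gt(dic$pD, 0)

  # degenerate single-draw posterior: pD = 0, DIC = Dbar
  fit1 <- run_mcmc(dat, model, iterations = 1, burn_in = 50, chains = 1,
                   seed = 13)
  dic1 <- compute_dic(fit1, dat)
  expect_equal(dic1$pD, 0, tolerance = 1e-8)
  expect_equal(dic1$DIC, dic1$Dbar, tolerance = 1e-8)
})

test_that("split-Rhat is computed per parameter and near 1 for long chains", {
  dat <- simulate_dataset(small_scenario(N = 50, T = 8), seed = 8)
  model <- pacf_model("stationary", a = 2, mean = "clm")
  fit <- run_mcmc(dat, model, iterations = 300, burn_in = 200, chains = 2,
                  seed = 15)
  rh <- split_rhat(fit)
  expect_named(rh, fit$param_names)
  expect_true(all(is.finite(rh)))
  expect_true(all(rh > 0.9))       # short chains: only sanity, not convergence
  expect_lt(median(rh), 1.25)
})

test_that("posterior CSV round-trips through write/read", {
  dat <- simulate_dataset(small_scenario(N = 25, T = 8), seed = 16)
  model <- pacf_model("stationary", a = 2, mean = "clm")
  fit <- run_mcmc(dat, model, iterations = 30, burn_in = 20, chains = 2,
                  seed = 17)
  path <- tempfile(fileext = ".csv")
  write_samples_csv(fit, path)
  fit2 <- read_samples_csv(path, dat, model)
  expect_equal(posterior_matrix(fit2), posterior_matrix(fit),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(compute_dic(fit2, dat)$DIC, compute_dic(fit, dat)$DIC,
               tolerance = 1e-8)
})
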