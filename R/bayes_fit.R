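#' Model specification
#'
#' Describes one of the three fitted model families:
#' `"stationary"` / `"nonstationary"` banded-PACF covariance models (serial
#' correlation through the PACF, log-linear marginal variance, random
#' intercept), or the `"lmm"` comparator (random intercept and slope with
#' modified-Cholesky covariance and independent residuals).  The mean is
#' either the conditional linear model in the observed dropout time
#' (`mean = "clm"`) or a dropout-free linear model (`mean = "simple"`), both
#' with intercept, time slope, dose effect and dose-by-time interaction.
#'
#' @param family model family.
#' @param a band width of the PACF (ignored for the LMM).
#' @param knots knot count or explicit locations for the thin-plate basis
#'   (non-stationary family); see [build_thin_plate_basis()].
#' @param spline_scale time scale for the spline basis (default
#'   `round(0.9 * T)`).
#' @param var_scale time scale of the log-linear variance model (default: the
#'   grid length).
#' @param mean `"clm"` or `"simple"`.
#' @param time_scale grid units per slope time unit (default 13: per-year
#'   slopes on a 4-week grid).
#' @param dropout_scale rescaling of the centered dropout time in the CLM.
#' @param quadratic_lag add a quadratic lag term to the stationary PACF model.
#' @return object of class `pacf_model`.
#' @export
pacf_model <- function(family = c("stationary", "nonstationary", "lmm"),
                       a = 2, knots = 10, spline_scale = NULL,
                       var_scale = NULL, mean = c("clm", "simple"),
                       time_scale = 13, dropout_scale = 100,
                       quadratic_lag = FALSE) {
  family <- match.arg(family)
  mean <- match.arg(mean)
  structure(list(family = family, a = as.integer(a), knots = knots,
                 spline_scale = spline_scale, var_scale = var_scale,
                 mean = mean, time_scale = time_scale,
                 dropout_scale = dropout_scale,
                 quadratic_lag = isTRUE(quadratic_lag)),
            class = "pacf_model")
}

#' Prior specification
#'
#' Independent Normal(0, `normal_sd`^2) priors on unconstrained location
#' parameters (mean coefficients, PACF regression coefficients, variance
#' coefficients, the LMM's lambda) and Uniform(0, `sd_upper`) priors on all
#' standard-deviation parameters.
#'
#' @param normal_sd prior SD for location parameters (default sqrt(1000)).
#' @param sd_upper upper bound of the uniform SD priors (default 20).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(normal_sd = sqrt(1000), sd_upper = 20) {
  if (normal_sd <= 0 || sd_upper <= 0) stop("prior bounds must be positive")
  structure(list(normal_sd = normal_sd, sd_upper = sd_upper),
            class = "prior_spec")
}

# ---------------------------------------------------------------------------
# fitting context: packed data, design matrix, basis, parameter naming

.make_context <- function(data, model) {
  stopifnot(inherits(data, "long_data"), inherits(model, "pacf_model"))
  pack <- .pack_data(data)
  T_len <- pack$T
  u <- (data$gridtime - 1) / model$time_scale
  dose <- data$dose
  dropout_center <- mean(pack$dropout)
  if (model$mean == "clm") {
    dstar <- (data$dropout - dropout_center) / model$dropout_scale
    X <- cbind(theta00 = 1, theta01 = dstar, theta10 = u, theta11 = u * dstar,
               theta20 = dose, theta21 = dose * dstar,
               theta30 = dose * u, theta31 = dose * u * dstar)
  } else {
    X <- cbind(beta0 = 1, beta1 = u, beta2 = dose, beta3 = dose * u)
  }
  basis <- NULL
  if (model$family == "nonstationary") {
    basis <- build_thin_plate_basis(T_len, knots = model$knots,
                                    scale = model$spline_scale)
  }
  var_scale <- if (is.null(model$var_scale)) T_len else model$var_scale
  state_names <- switch(model$family,
    stationary = c("gamma0", "gamma1",
                   if (model$quadratic_lag) "gamma2",
                   "alpha0", "alpha1", "sigma_b"),
    nonstationary = c("g0_int", "g0_lin", paste0("xi0_", seq_len(basis$K)),
                      "g1_int", "g1_lin", paste0("xi1_", seq_len(basis$K)),
                      "alpha0", "alpha1", "sigma_b", "sigma_g0", "sigma_g1"),
    lmm = c("lambda", "sigma0", "sigma_e", "sigma_eps"))
  list(pack = pack, X = X, basis = basis, T = T_len, var_scale = var_scale,
       model = model, dropout_center = dropout_center,
       theta_names = colnames(X), state_names = state_names)
}

# Covariance structures (full-grid correlation-or-covariance matrix, marginal
# SDs, random-intercept SD, nugget) from a named state vector; NULL when the
# state violates a constraint or evaluates outside the PACF domain.
.cov_structures <- function(state, ctx, R_cache = NULL) {
  model <- ctx$model
  if (model$family == "lmm") {
    if (state["sigma0"] <= 0 || state["sigma_e"] <= 0 || state["sigma_eps"] <= 0) {
      return(NULL)
    }
    lp <- lmm_params(state[["lambda"]], state[["sigma0"]], state[["sigma_e"]],
                     state[["sigma_eps"]], time_scale = model$time_scale)
    tt <- seq_len(ctx$T)
    Zt <- cbind(1, (tt - 1) / model$time_scale)
    Cfull <- Zt %*% lmm_G(lp) %*% t(Zt)
    return(list(R = Cfull, sd = rep(1, ctx$T), sigma_b = 0,
                nugget = state[["sigma_eps"]]^2))
  }
  if (state["sigma_b"] < 0) return(NULL)
  cp <- tryCatch({
    if (model$family == "stationary") {
      ga <- c(state[["gamma0"]], state[["gamma1"]],
              if (model$quadratic_lag) state[["gamma2"]])
      cov_params("stationary", a = model$a, gamma = ga,
                 alpha = c(state[["alpha0"]], state[["alpha1"]]),
                 sigma_b = state[["sigma_b"]], var_scale = ctx$var_scale)
    } else {
      K <- ctx$basis$K
      cov_params("nonstationary", a = model$a,
                 g0_fixed = c(state[["g0_int"]], state[["g0_lin"]]),
                 g0_xi = state[paste0("xi0_", seq_len(K))],
                 g1_fixed = c(state[["g1_int"]], state[["g1_lin"]]),
                 g1_xi = state[paste0("xi1_", seq_len(K))],
                 alpha = c(state[["alpha0"]], state[["alpha1"]]),
                 sigma_b = state[["sigma_b"]],
                 sigma_g0 = max(state[["sigma_g0"]], 0),
                 sigma_g1 = max(state[["sigma_g1"]], 0),
                 var_scale = ctx$var_scale)
    }
  }, error = function(e) NULL)
  if (is.null(cp)) return(NULL)
  if (is.null(R_cache)) {
    p <- tryCatch(evaluate_pacf(cp, grid_length = ctx$T, basis = ctx$basis),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    R <- pacf_to_corr_cpp(p$pi, p$a)
  } else {
    R <- R_cache  # proposal leaves the PACF block untouched
  }
  sd <- sqrt(evaluate_variance(cp, seq_len(ctx$T), grid_length = ctx$T))
  list(R = R, sd = sd, sigma_b = state[["sigma_b"]], nugget = 0)
}

.loglik_ctx <- function(theta, state, ctx, cs = NULL, want_chi2 = FALSE) {
  if (is.null(cs)) cs <- .cov_structures(state, ctx)
  if (is.null(cs)) return(list(loglik = -Inf, chi2 = Inf))
  mu <- drop(ctx$X %*% theta)
  gauss_profile_cpp(ctx$pack$y, mu, ctx$pack$tidx, ctx$pack$start,
                    cs$R, cs$sd, cs$sigma_b, cs$nugget)
}

#' Marginal log-likelihood
#'
#' Sum over subjects of the multivariate normal log density with mean from the
#' mean model and covariance from the covariance model, the random intercept
#' integrated out analytically (it appears as \eqn{\sigma_b^2 J} inside each
#' subject's covariance).  For the LMM both random effects are integrated out.
#'
#' @param data a [long_data()] object.
#' @param params named numeric vector holding the mean coefficients and the
#'   covariance-block parameters, using the same names as the posterior draws
#'   of [run_mcmc()] (e.g. `theta00..theta31, gamma0, gamma1, alpha0, alpha1,
#'   sigma_b` for the stationary CLM model).
#' @param model a [pacf_model()] object.
#' @return scalar log-likelihood; `-Inf` (with a warning) if a subject
#'   covariance is not positive definite.
#' @export
log_marginal_likelihood <- function(data, params, model) {
  ctx <- .make_context(data, model)
  need <- c(ctx$theta_names, ctx$state_names)
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("params is missing: ", paste(miss, collapse = ", "))
  out <- .loglik_ctx(params[ctx$theta_names], params[ctx$state_names], ctx)
  if (!is.finite(out$loglik)) warning("covariance not positive definite; log-likelihood is -Inf")
  out$loglik
}

# ---------------------------------------------------------------------------
# initialization

.init_state <- function(ctx, priors) {
  model <- ctx$model
  X <- ctx$X
  y <- ctx$pack$y
  theta <- tryCatch(qr.solve(qr(X), y), error = function(e) rep(0, ncol(X)))
  theta[!is.finite(theta)] <- 0
  names(theta) <- ctx$theta_names
  r <- y - drop(X %*% theta)
  id <- rep(seq_len(ctx$pack$N), diff(ctx$pack$start))
  rw <- r - stats::ave(r, id)                     # within-subject residuals
  sb <- stats::sd(tapply(r, id, mean))
  if (!is.finite(sb)) sb <- 1
  sb <- min(max(sb, 0.05), 0.8 * priors$sd_upper)

  gt <- ctx$pack$tidx + 1L
  vt <- tapply(rw, gt, stats::var)
  vt <- vt[is.finite(vt) & vt > 0]
  if (length(vt) >= 3) {
    tv <- as.numeric(names(vt)) / ctx$var_scale
    fit <- stats::lm.fit(cbind(1, tv), log(as.numeric(vt)))
    alpha <- fit$coefficients
  } else {
    alpha <- c(log(max(stats::var(rw), 1e-4)), 0)
  }
  alpha[!is.finite(alpha)] <- 0

  # lag-1 correlation of standardized within-subject residuals
  z <- rw / sqrt(pmax(exp(alpha[1] + alpha[2] * gt / ctx$var_scale), 1e-8))
  prev <- c(NA, z[-length(z)])
  same <- c(FALSE, diff(id) == 0 & diff(gt) == 1)
  r1 <- if (sum(same) > 10) stats::cor(z[same], prev[same]) else 0.3
  if (!is.finite(r1)) r1 <- 0.3
  r1 <- min(max(r1, -0.9), 0.9)
  z1 <- atanh(r1)

  state <- switch(model$family,
    stationary = {
      s <- c(gamma0 = z1 + 0.1, gamma1 = -0.1,
             if (model$quadratic_lag) c(gamma2 = 0),
             alpha0 = unname(alpha[1]), alpha1 = unname(alpha[2]),
             sigma_b = sb)
      s
    },
    nonstationary = {
      K <- ctx$basis$K
      c(stats::setNames(c(z1 + 0.1, 0), c("g0_int", "g0_lin")),
        stats::setNames(rep(0, K), paste0("xi0_", seq_len(K))),
        stats::setNames(c(-0.1, 0), c("g1_int", "g1_lin")),
        stats::setNames(rep(0, K), paste0("xi1_", seq_len(K))),
        alpha0 = unname(alpha[1]), alpha1 = unname(alpha[2]),
        sigma_b = sb, sigma_g0 = 0.5, sigma_g1 = 0.5)
    },
    lmm = c(lambda = 0, sigma0 = sb,
            sigma_e = min(max(0.5 * sb, 0.05), 0.8 * priors$sd_upper),
            sigma_eps = min(max(stats::sd(rw), 0.05), 0.8 * priors$sd_upper)))
  state <- state[ctx$state_names]
  list(theta = theta, state = state)
}

# MH blocks (index sets into the state vector), initial step scales, and
# whether the block learns a full proposal covariance during burn-in.  The
# serial-correlation strength, variance level and random-intercept SD are
# strongly correlated a posteriori (slowly decaying serial correlation can
# mimic a random intercept), so they are proposed jointly with an adaptive
# covariance rather than as independent scalar walks.
.mh_blocks <- function(ctx) {
  model <- ctx$model
  switch(model$family,
    stationary = {
      gpar <- c("gamma0", "gamma1", if (model$quadratic_lag) "gamma2")
      list(
        gamma = list(par = gpar, step = 0.08),
        alpha = list(par = c("alpha0", "alpha1"), step = 0.08),
        sigma_b = list(par = "sigma_b", step = 0.4),
        joint = list(par = c(gpar, "alpha0", "alpha1", "sigma_b"),
                     step = 1, adapt_cov = TRUE))
    },
    nonstationary = {
      K <- ctx$basis$K
      list(
        g0_fixed = list(par = c("g0_int", "g0_lin"), step = 0.08),
        g0_xi = list(par = paste0("xi0_", seq_len(K)), step = 0.05),
        g1_fixed = list(par = c("g1_int", "g1_lin"), step = 0.06),
        g1_xi = list(par = paste0("xi1_", seq_len(K)), step = 0.04),
        alpha = list(par = c("alpha0", "alpha1"), step = 0.08),
        sigma_b = list(par = "sigma_b", step = 0.4),
        joint = list(par = c("g0_int", "g0_lin", "g1_int", "g1_lin",
                             "alpha0", "alpha1", "sigma_b"),
                     step = 1, adapt_cov = TRUE))
    },
    lmm = list(
      lambda = list(par = "lambda", step = 0.1),
      sigma0 = list(par = "sigma0", step = 0.4),
      sigma_e = list(par = "sigma_e", step = 0.2),
      sigma_eps = list(par = "sigma_eps", step = 0.1),
      joint = list(par = c("lambda", "sigma0", "sigma_e", "sigma_eps"),
                   step = 1, adapt_cov = TRUE)))
}

# diagonal fallback scales for the adaptive blocks before enough burn-in
# draws have accumulated
.block_init_scales <- function(par) {
  s <- rep(0.08, length(par))
  s[grepl("^sigma", par)] <- 0.3
  s
}

# log prior of the covariance-block state (terms that change within MH blocks)
.log_prior_state <- function(state, ctx, priors) {
  model <- ctx$model
  v <- priors$normal_sd^2
  lp <- 0
  norm_term <- function(x) -sum(x^2) / (2 * v)
  if (model$family == "stationary") {
    if (state[["gamma1"]] > 0) return(-Inf)
    if (state[["sigma_b"]] <= 0 || state[["sigma_b"]] >= priors$sd_upper) return(-Inf)
    lp <- lp + norm_term(state[c("gamma0", "gamma1")]) +
      norm_term(state[c("alpha0", "alpha1")])
    if (model$quadratic_lag) lp <- lp + norm_term(state[["gamma2"]])
  } else if (model$family == "nonstationary") {
    if (state[["sigma_b"]] <= 0 || state[["sigma_b"]] >= priors$sd_upper) return(-Inf)
    sg0 <- state[["sigma_g0"]]; sg1 <- state[["sigma_g1"]]
    if (sg0 <= 0 || sg0 >= priors$sd_upper || sg1 <= 0 || sg1 >= priors$sd_upper) {
      return(-Inf)
    }
    K <- ctx$basis$K
    xi0 <- state[paste0("xi0_", seq_len(K))]
    xi1 <- state[paste0("xi1_", seq_len(K))]
    lp <- lp + norm_term(state[c("g0_int", "g0_lin", "g1_int", "g1_lin")]) +
      norm_term(state[c("alpha0", "alpha1")]) -
      K * log(sg0) - sum(xi0^2) / (2 * sg0^2) -
      K * log(sg1) - sum(xi1^2) / (2 * sg1^2)
  } else {
    for (nm in c("sigma0", "sigma_e", "sigma_eps")) {
      if (state[[nm]] <= 0 || state[[nm]] >= priors$sd_upper) return(-Inf)
    }
    lp <- lp + norm_term(state[["lambda"]])
  }
  lp
}

# truncated conditional draw of a smoothing SD: sigma^2 | xi is inverse-gamma
# ((K-1)/2, sum(xi^2)/2) restricted to (floor, sd_upper)
.draw_smooth_sd <- function(xi, sd_upper, floor_sd = 0.01) {
  K <- length(xi)
  S <- max(sum(xi^2), 1e-10)
  shape <- (K - 1) / 2
  rate <- S / 2
  lo <- stats::pgamma(1 / sd_upper^2, shape, rate = rate)
  hi <- stats::pgamma(1 / floor_sd^2, shape, rate = rate)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) return(floor_sd)
  u <- stats::runif(1, lo, hi)
  x <- stats::qgamma(u, shape, rate = rate)
  1 / sqrt(x)
}

# ---------------------------------------------------------------------------

#' Run the MCMC sampler
#'
#' Mean coefficients are updated by their conjugate Gaussian full conditional
#' given the current covariance; covariance-block parameters are updated by
#' random-walk Metropolis with per-block step sizes adapted during burn-in
#' only (target acceptance 0.35, adaptation frozen afterwards so the
#' post-burn-in chain is a valid Markov chain); smoothing SDs of the spline
#' blocks are updated by a truncated conjugate draw.  Proposals violating
#' model constraints (e.g. \eqn{g_{t1} > 0}, SDs outside their uniform prior
#' support) are rejected.  Runs are fully reproducible: the same seed yields
#' identical chains.
#'
#' @param data a [long_data()] object.
#' @param model a [pacf_model()] object.
#' @param priors a [prior_spec()] object.
#' @param iterations post-burn-in iterations per chain (`0` returns the
#'   initial state only).
#' @param burn_in burn-in iterations per chain.
#' @param chains number of chains (>= 2 recommended for diagnostics).
#' @param seed integer seed.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param verbose print progress.
#' @return object of class `pacf_fit`: per-chain draw matrices (one named
#'   column per parameter) and log-likelihood traces, acceptance rates per
#'   Metropolis block, the model/prior/config metadata, and the thin-plate
#'   basis where applicable.
#' @export
run_mcmc <- function(data, model, priors = prior_spec(),
                     iterations = 2000, burn_in = 1000, chains = 2,
                     seed = 1, thin = 1, verbose = FALSE) {
  ctx <- .make_context(data, model)
  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, chains)
  chains_out <- vector("list", chains)
  accept_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res <- .run_chain(ctx, priors, iterations, burn_in, thin,
                      jitter = (ch > 1), verbose = verbose, chain_id = ch)
    chains_out[[ch]] <- res[c("draws", "loglik")]
    accept_out[[ch]] <- res$acceptance
  }
  structure(list(chains = chains_out,
                 acceptance = accept_out,
                 param_names = c(ctx$theta_names, ctx$state_names),
                 theta_names = ctx$theta_names, state_names = ctx$state_names,
                 model = model, priors = priors, basis = ctx$basis,
                 dropout_center = ctx$dropout_center, T = ctx$T,
                 mcmc = list(iterations = iterations, burn_in = burn_in,
                             chains = chains, seed = seed, thin = thin)),
            class = "pacf_fit")
}

.run_chain <- function(ctx, priors, iterations, burn_in, thin, jitter,
                       verbose = FALSE, chain_id = 1) {
  init <- .init_state(ctx, priors)
  theta <- init$theta
  state <- init$state
  if (jitter) {
    loc <- !grepl("^sigma", names(state))
    state[loc] <- state[loc] + stats::rnorm(sum(loc), 0, 0.05)
    state[!loc] <- state[!loc] * exp(stats::rnorm(sum(!loc), 0, 0.1))
    if ("gamma1" %in% names(state)) state["gamma1"] <- -abs(state["gamma1"])
    if ("g1_int" %in% names(state)) state["g1_int"] <- -abs(state["g1_int"])
  }
  # re-initialize (shrinking towards a safe state) if the likelihood diverges
  for (try in 0:10) {
    cs <- .cov_structures(state, ctx)
    ll <- .loglik_ctx(theta, state, ctx, cs)$loglik
    if (is.finite(ll)) break
    if (try == 10) stop("could not find a valid initial state")
    shrink <- grepl("^(gamma|g0|g1|xi)", names(state))
    state[shrink] <- state[shrink] * 0.5
    state[grepl("^sigma", names(state))] <-
      pmin(pmax(state[grepl("^sigma", names(state))], 0.05),
           priors$sd_upper * 0.9)
  }

  param_names <- c(ctx$theta_names, ctx$state_names)
  if (iterations == 0) {
    draws <- matrix(c(theta, state), nrow = 1,
                    dimnames = list(NULL, param_names))
    return(list(draws = draws, loglik = ll, acceptance = numeric(0)))
  }

  blocks <- .mh_blocks(ctx)
  steps <- vapply(blocks, `[[`, numeric(1), "step")
  acc_win <- tot_win <- stats::setNames(numeric(length(blocks)), names(blocks))
  acc_post <- tot_post <- acc_win
  # adaptive-covariance bookkeeping (burn-in only)
  adapt <- lapply(blocks, function(b) {
    d <- length(b$par)
    list(on = isTRUE(b$adapt_cov), n = 0, mean = numeric(d),
         M2 = matrix(0, d, d), L = diag(.block_init_scales(b$par), d))
  })
  n_keep <- floor(iterations / thin)
  draws <- matrix(NA_real_, n_keep, length(param_names),
                  dimnames = list(NULL, param_names))
  ll_keep <- numeric(n_keep)
  kept <- 0L
  v_prior <- priors$normal_sd^2
  nonstat <- ctx$model$family == "nonstationary"
  K <- if (nonstat) ctx$basis$K else 0L

  total_iter <- burn_in + iterations
  for (iter in seq_len(total_iter)) {
    in_burn <- iter <= burn_in

    # --- conjugate Gaussian update of the mean coefficients
    suff <- xtsx_cpp(ctx$pack$y, ctx$X, ctx$pack$tidx, ctx$pack$start,
                     cs$R, cs$sd, cs$sigma_b, cs$nugget)
    A <- suff$XtSX + diag(1 / v_prior, ncol(ctx$X))
    cholA <- chol(A)
    m <- backsolve(cholA, forwardsolve(t(cholA), suff$XtSy))
    theta <- m + backsolve(cholA, stats::rnorm(length(m)))
    names(theta) <- ctx$theta_names
    ll <- .loglik_ctx(theta, state, ctx, cs)$loglik
    lpri <- .log_prior_state(state, ctx, priors)

    # --- random-walk Metropolis on the covariance blocks
    for (b in seq_along(blocks)) {
      par <- blocks[[b]]$par
      prop <- state
      prop[par] <- prop[par] +
        steps[b] * drop(adapt[[b]]$L %*% stats::rnorm(length(par)))
      lpri_prop <- .log_prior_state(prop, ctx, priors)
      tot_win[b] <- tot_win[b] + 1
      if (!in_burn) tot_post[b] <- tot_post[b] + 1
      if (is.finite(lpri_prop)) {
        reuse_R <- ctx$model$family != "lmm" &&
          all(par %in% c("alpha0", "alpha1", "sigma_b"))
        cs_prop <- .cov_structures(prop, ctx,
                                   R_cache = if (reuse_R) cs$R else NULL)
        ll_prop <- if (is.null(cs_prop)) -Inf else
          .loglik_ctx(theta, prop, ctx, cs_prop)$loglik
        if (is.finite(ll_prop) &&
            log(stats::runif(1)) < (ll_prop + lpri_prop) - (ll + lpri)) {
          state <- prop
          cs <- cs_prop
          ll <- ll_prop
          lpri <- lpri_prop
          acc_win[b] <- acc_win[b] + 1
          if (!in_burn) acc_post[b] <- acc_post[b] + 1
        }
      }
      # adapt during burn-in only: step scale every 25 proposals, and for
      # joint blocks a full proposal covariance learned from the chain
      if (in_burn) {
        if (adapt[[b]]$on) {
          a_b <- adapt[[b]]
          x <- state[par]
          a_b$n <- a_b$n + 1
          dlt <- x - a_b$mean
          a_b$mean <- a_b$mean + dlt / a_b$n
          a_b$M2 <- a_b$M2 + tcrossprod(dlt, x - a_b$mean)
          if (a_b$n >= 50 && a_b$n %% 25 == 0) {
            C <- a_b$M2 / (a_b$n - 1) + diag(1e-8, length(par))
            Lc <- tryCatch(t(chol(C)), error = function(e) NULL)
            if (!is.null(Lc)) a_b$L <- (2.38 / sqrt(length(par))) * Lc
          }
          adapt[[b]] <- a_b
        }
        if (tot_win[b] >= 25) {
          rate <- acc_win[b] / tot_win[b]
          steps[b] <- min(max(steps[b] * exp(0.8 * (rate - 0.35)), 1e-4), 10)
          acc_win[b] <- tot_win[b] <- 0
        }
      }
    }

    # --- conjugate truncated draw of the smoothing SDs (non-stationary)
    if (nonstat) {
      state[["sigma_g0"]] <- .draw_smooth_sd(state[paste0("xi0_", seq_len(K))],
                                             priors$sd_upper)
      state[["sigma_g1"]] <- .draw_smooth_sd(state[paste0("xi1_", seq_len(K))],
                                             priors$sd_upper)
      lpri <- .log_prior_state(state, ctx, priors)
    }

    if (!in_burn && ((iter - burn_in) %% thin == 0)) {
      kept <- kept + 1L
      draws[kept, ] <- c(theta, state)
      ll_keep[kept] <- ll
    }
    if (verbose && iter %% 500 == 0) {
      message(sprintf("chain %d: iteration %d / %d, loglik %.1f",
                      chain_id, iter, total_iter, ll))
    }
  }
  acceptance <- ifelse(tot_post > 0, acc_post / tot_post, NA_real_)
  names(acceptance) <- names(blocks)
  list(draws = draws[seq_len(kept), , drop = FALSE],
       loglik = ll_keep[seq_len(kept)], acceptance = acceptance)
}

#' Pooled posterior draws
#'
#' @param fit a `pacf_fit` object.
#' @return matrix of pooled post-burn-in draws (chains stacked), one named
#'   column per parameter.
#' @export
posterior_matrix <- function(fit) {
  stopifnot(inherits(fit, "pacf_fit"))
  do.call(rbind, lapply(fit$chains, `[[`, "draws"))
}

#' Posterior summary table
#'
#' @param fit a `pacf_fit` object.
#' @return data.frame with posterior mean, SD, median and central 95% interval
#'   per parameter, plus split-Rhat when at least two chains were run.
#' @export
posterior_summary <- function(fit) {
  draws <- posterior_matrix(fit)
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2, stats::sd),
                    median = qs[, 1], lower95 = qs[, 2], upper95 = qs[, 3],
                    row.names = NULL)
  if (length(fit$chains) >= 2) out$rhat <- split_rhat(fit)
  out
}

#' Split-Rhat convergence diagnostic
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' factor is computed across the resulting sequences.  Values near 1 indicate
#' convergence; above about 1.01 is advisory of trouble.
#'
#' @param fit a `pacf_fit` object.
#' @return named vector of Rhat values.
#' @export
split_rhat <- function(fit) {
  stopifnot(inherits(fit, "pacf_fit"))
  halves <- list()
  for (chain in fit$chains) {
    d <- chain$draws
    n <- nrow(d)
    if (n < 4) return(stats::setNames(rep(NA_real_, ncol(d)), colnames(d)))
    h <- floor(n / 2)
    halves <- c(halves, list(d[1:h, , drop = FALSE],
                             d[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  vapply(seq_along(fit$param_names), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W < 1e-300) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) -> rh
  stats::setNames(rh, fit$param_names)
}

#' Deviance information criterion
#'
#' \eqn{\bar D} is the posterior mean of the deviance
#' \eqn{-2 \log L(\text{params})} over the stored draws, \eqn{\hat D} the
#' deviance at the posterior means of the parameters,
#' \eqn{p_D = \bar D - \hat D} the effective number of parameters, and
#' \eqn{DIC = \bar D + p_D}.  The likelihood is the marginal one: random
#' effects are integrated out analytically.
#'
#' @param fit a `pacf_fit` object.
#' @param data the [long_data()] object the model was fitted to.
#' @return object of class `dic_report` with fields `Dbar`, `Dhat`, `pD`,
#'   `DIC`.
#' @export
compute_dic <- function(fit, data) {
  stopifnot(inherits(fit, "pacf_fit"))
  ll <- unlist(lapply(fit$chains, `[[`, "loglik"))
  Dbar <- mean(-2 * ll)
  pm <- colMeans(posterior_matrix(fit))
  Dhat <- -2 * log_marginal_likelihood(data, pm, fit$model)
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("Dbar = %.1f, Dhat = %.1f, pD = %.1f, DIC = %.1f\n",
              x$Dbar, x$Dhat, x$pD, x$DIC))
  invisible(x)
}

#' Write posterior draws to CSV
#'
#' One row per stored draw, one column per named parameter plus `chain` and
#' `loglik` columns.
#'
#' @param fit a `pacf_fit` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(fit, path) {
  stopifnot(inherits(fit, "pacf_fit"))
  tabs <- lapply(seq_along(fit$chains), function(ch) {
    d <- as.data.frame(fit$chains[[ch]]$draws)
    d$chain <- ch
    d$loglik <- fit$chains[[ch]]$loglik
    d
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Rebuild a fit object from a posterior CSV
#'
#' Companion to [write_samples_csv()]: reads a draw table written by the CLI
#' or by that function so that [compute_dic()], [ppc_chi2()] and
#' [marginal_effects()] can run on stored output.
#'
#' @param path CSV written by [write_samples_csv()].
#' @param data the dataset the posterior belongs to.
#' @param model the [pacf_model()] the posterior was drawn from.
#' @return a `pacf_fit` object (acceptance rates unavailable).
#' @export
read_samples_csv <- function(path, data, model) {
  tab <- utils::read.csv(path)
  ctx <- .make_context(data, model)
  need <- c(ctx$theta_names, ctx$state_names)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("posterior file is missing columns: ",
                         paste(miss, collapse = ", "))
  chains <- sort(unique(tab$chain))
  ch_out <- lapply(chains, function(ch) {
    sub <- tab[tab$chain == ch, , drop = FALSE]
    list(draws = as.matrix(sub[, need, drop = FALSE]),
         loglik = if ("loglik" %in% names(sub)) sub$loglik else
           rep(NA_real_, nrow(sub)))
  })
  structure(list(chains = ch_out, acceptance = NULL,
                 param_names = need, theta_names = ctx$theta_names,
                 state_names = ctx$state_names, model = model,
                 priors = prior_spec(), basis = ctx$basis,
                 dropout_center = ctx$dropout_center, T = ctx$T,
                 mcmc = list(iterations = nrow(ch_out[[1]]$draws),
                             burn_in = NA, chains = length(chains),
                             seed = NA, thin = 1)),
            class = "pacf_fit")
}
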