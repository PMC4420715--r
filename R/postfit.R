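#' Bayesian bootstrap weights
#'
#' One draw of Dirichlet(1, ..., 1) weights over `n` observed values,
#' representing posterior uncertainty about a completely unspecified discrete
#' distribution supported on them.
#'
#' @param n number of support points (>= 1).
#' @return non-negative weight vector summing to one.
#' @export
bayesian_bootstrap_weights <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive count")
  e <- stats::rexp(n)
  e / sum(e)
}

#' Marginal covariate effects by the Bayesian bootstrap
#'
#' The conditional linear model gives dropout-conditional coefficients
#' \eqn{\beta_k(d)}; marginal effects average them over the (unspecified)
#' dropout-time distribution, represented per dose group by Dirichlet(1,...,1)
#' weights over that group's observed dropout times, redrawn at every
#' posterior draw.  The returned 4-vector per draw is: marginal intercept and
#' time slope of the reference (dose = 0) group, and the marginal dose and
#' dose-by-time contrasts (dose-group averages minus reference averages).
#'
#' @param fit a `pacf_fit` object with a CLM mean.
#' @param data the fitted [long_data()] dataset (supplies per-subject dropout
#'   times and dose labels).
#' @param seed integer seed for the bootstrap weights.
#' @return object of class `marginal_effects`: per-draw effects plus posterior
#'   medians and central 95% intervals.
#' @export
marginal_effects <- function(fit, data, seed = 1) {
  stopifnot(inherits(fit, "pacf_fit"))
  if (fit$model$mean != "clm") stop("marginal effects require a CLM mean structure")
  pack <- .pack_data(data)
  d0 <- pack$dropout[pack$dose == 0]
  d1 <- pack$dropout[pack$dose == 1]
  if (length(d0) == 0 || length(d1) == 0) stop("both dose groups must be non-empty")
  draws <- posterior_matrix(fit)
  th <- draws[, c("theta00", "theta01", "theta10", "theta11",
                  "theta20", "theta21", "theta30", "theta31"), drop = FALSE]
  s0 <- (d0 - fit$dropout_center) / fit$model$dropout_scale
  s1 <- (d1 - fit$dropout_center) / fit$model$dropout_scale
  set.seed(seed)
  out <- matrix(NA_real_, nrow(th), 4,
                dimnames = list(NULL, c("intercept", "slope", "dose", "dose_slope")))
  for (i in seq_len(nrow(th))) {
    w0 <- bayesian_bootstrap_weights(length(s0))
    w1 <- bayesian_bootstrap_weights(length(s1))
    m0i <- sum(w0 * (th[i, "theta00"] + th[i, "theta01"] * s0))
    m0s <- sum(w0 * (th[i, "theta10"] + th[i, "theta11"] * s0))
    m1i <- sum(w1 * (th[i, "theta00"] + th[i, "theta01"] * s1 +
                       th[i, "theta20"] + th[i, "theta21"] * s1))
    m1s <- sum(w1 * (th[i, "theta10"] + th[i, "theta11"] * s1 +
                       th[i, "theta30"] + th[i, "theta31"] * s1))
    out[i, ] <- c(m0i, m0s, m1i - m0i, m1s - m0s)
  }
  qs <- apply(out, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  structure(list(draws = out,
                 summary = data.frame(effect = colnames(out),
                                      median = qs[1, ], lower95 = qs[2, ],
                                      upper95 = qs[3, ], row.names = NULL)),
            class = "marginal_effects")
}

#' @export
print.marginal_effects <- function(x, ...) {
  cat("Marginal covariate effects (Bayesian bootstrap over dropout times)\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Chi-square discrepancy of a dataset under given parameters
#'
#' \eqn{\chi^2 = \sum_i (y_i - \mu_i)' \Sigma_i^{-1} (y_i - \mu_i)} with the
#' subject-level marginal mean and covariance (random effects integrated
#' out).  Under the true model \eqn{\chi^2} is chi-square with `n` (total
#' observations) degrees of freedom.
#'
#' @param data a [long_data()] object.
#' @param params named parameter vector (see [log_marginal_likelihood()]).
#' @param model a [pacf_model()] object.
#' @return list with `chi2` and `n`.
#' @export
chi2_discrepancy <- function(data, params, model) {
  ctx <- .make_context(data, model)
  out <- .loglik_ctx(params[ctx$theta_names], params[ctx$state_names], ctx,
                     want_chi2 = TRUE)
  list(chi2 = out$chi2, n = length(ctx$pack$y))
}

#' Chi-square posterior predictive check
#'
#' For each retained posterior draw: (1) sample a replicated dropout time per
#' subject from the empirical dropout distribution; (2) build replicated
#' measurement times starting at grid point 1 (enrollment) and adding gap
#' times resampled from the pooled empirical gap distribution until the
#' dropout time is exceeded; (3) simulate replicated responses from the model
#' at those times given the replicated dropout time and the draw's
#' parameters (dose labels are reused: dose is a design variable); (4) compute
#' the chi-square discrepancy of the replicated and the observed data under
#' the draw's parameters; the posterior predictive probability (ppp) is the
#' fraction of draws whose replicated discrepancy exceeds the observed one.
#' A ppp near 0.5 indicates adequate fit; values near 0 or 1 indicate
#' discrepancy the model cannot reproduce.
#'
#' Subjects are processed in a canonical (sorted id) order, so the result does
#' not depend on row order in `data`.
#'
#' @param fit a `pacf_fit` object.
#' @param data the fitted [long_data()] dataset.
#' @param n_draws number of posterior draws to use (evenly thinned from the
#'   pooled draws).
#' @param seed integer seed for the replication randomness.
#' @return object of class `ppc_report`: `ppp`, and the per-draw
#'   (`chi2_rep`, `chi2_obs`) pairs.
#' @export
ppc_chi2 <- function(fit, data, n_draws = 200, seed = 1) {
  stopifnot(inherits(fit, "pacf_fit"))
  ctx <- .make_context(data, fit$model)
  pack <- ctx$pack
  ord <- order(pack$ids)
  dropout <- pack$dropout[ord]
  dose <- pack$dose[ord]
  N <- pack$N
  res <- attr(data, "resolution")
  gaps <- unlist(lapply(seq_len(N), function(i) {
    s <- pack$start[i] + 1
    e <- pack$start[i + 1]
    if (e > s) diff(pack$tidx[s:e]) else integer(0)
  }), use.names = FALSE)
  if (length(gaps) == 0) stop("no gap times observed; cannot replicate measurement schedules")

  draws <- posterior_matrix(fit)
  idx <- unique(round(seq(1, nrow(draws), length.out = min(n_draws, nrow(draws)))))
  set.seed(seed)
  chi2_rep <- chi2_obs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    par <- draws[idx[k], ]
    theta <- par[ctx$theta_names]
    state <- par[ctx$state_names]
    cs <- .cov_structures(state, ctx)
    if (is.null(cs)) { chi2_rep[k] <- NA; chi2_obs[k] <- NA; next }
    mu_obs <- drop(ctx$X %*% theta)
    chi2_obs[k] <- gauss_profile_cpp(pack$y, mu_obs, pack$tidx, pack$start,
                                     cs$R, cs$sd, cs$sigma_b, cs$nugget)$chi2

    d_rep <- dropout[sample.int(N, N, replace = TRUE)]
    y_all <- list(); t_all <- list(); mu_all <- list()
    start_rep <- integer(N + 1)
    for (i in seq_len(N)) {
      tmax <- max(1L, floor(d_rep[i] / res))
      times <- 1L
      repeat {
        nxt <- times[length(times)] + gaps[sample.int(length(gaps), 1)]
        if (nxt > min(tmax, ctx$T)) break
        times <- c(times, nxt)
      }
      mu_i <- .mean_for_subject(theta, times, dose[i], d_rep[i], ctx)
      S <- .sigma_for_times(cs, times)
      L <- chol(S)
      y_i <- mu_i + drop(stats::rnorm(length(times)) %*% L)
      y_all[[i]] <- y_i; mu_all[[i]] <- mu_i; t_all[[i]] <- times
      start_rep[i + 1] <- start_rep[i] + length(times)
    }
    chi2_rep[k] <- gauss_profile_cpp(unlist(y_all), unlist(mu_all),
                                     as.integer(unlist(t_all)) - 1L, start_rep,
                                     cs$R, cs$sd, cs$sigma_b, cs$nugget)$chi2
  }
  ok <- is.finite(chi2_rep) & is.finite(chi2_obs)
  structure(list(ppp = mean(chi2_rep[ok] > chi2_obs[ok]),
                 chi2_rep = chi2_rep, chi2_obs = chi2_obs,
                 n_draws = sum(ok)),
            class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf("posterior predictive check: ppp = %.3f (%d draws)\n",
              x$ppp, x$n_draws))
  invisible(x)
}

# mean vector for one (possibly replicated) subject under the fitted mean model
.mean_for_subject <- function(theta, times, dose, d, ctx) {
  u <- (times - 1) / ctx$model$time_scale
  if (ctx$model$mean == "clm") {
    ds <- (d - ctx$dropout_center) / ctx$model$dropout_scale
    b0 <- theta[["theta00"]] + theta[["theta01"]] * ds
    b1 <- theta[["theta10"]] + theta[["theta11"]] * ds
    b2 <- theta[["theta20"]] + theta[["theta21"]] * ds
    b3 <- theta[["theta30"]] + theta[["theta31"]] * ds
    b0 + b1 * u + b2 * dose + b3 * dose * u
  } else {
    theta[["beta0"]] + theta[["beta1"]] * u + theta[["beta2"]] * dose +
      theta[["beta3"]] * dose * u
  }
}

.sigma_for_times <- function(cs, times) {
  sd_t <- cs$sd[times]
  S <- cs$sigma_b^2 + outer(sd_t, sd_t) * cs$R[times, times, drop = FALSE]
  if (cs$nugget > 0) S <- S + diag(cs$nugget, length(times))
  S
}
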