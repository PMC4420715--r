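---
title: "Modeling the covariance of irregular longitudinal data through partial autocorrelations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the covariance of irregular longitudinal data through partial autocorrelations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacfcov)
```

## The problem

In long-term follow-up studies subjects are measured at uncommon, irregularly
spaced times, and often stop being measured for reasons related to their
outcomes.  Two standard settings make the covariance model load-bearing for
*mean* inference: outcome-dependent follow-up (visit frequency depends on past
outcomes) and ignorable missingness.  In both, likelihood-based mean estimates
are consistent only when the full joint distribution — including the
covariance function — is correctly specified.  Unstructured covariance
estimation is infeasible when there are hundreds of distinct observation
times, and parametric stationary structures are often too rigid.

`pacfcov` models the covariance function of a discrete-time Gaussian process
$\{Y_i(t): t = 1, \dots, T\}$ through its **partial autocorrelation function**
(PACF): $\pi(t, t+j)$ is the correlation of $Y(t)$ and $Y(t+j)$ given the
intervening values $Y(t+1), \dots, Y(t+j-1)$.  Unlike marginal correlations,
the partial autocorrelations are variation independent: *any* configuration in
$(-1,1)^{T(T-1)/2}$ induces a valid positive-definite correlation matrix.
Modeling on this scale removes the positive-definiteness constraint entirely.

## Covariance model

The marginal covariance of a subject observed at grid times
$t_{i1} < \dots < t_{in_i}$ is

$$\Sigma_i = \sigma_b^2 J + S_i R_i S_i,$$

where $J$ is the all-ones matrix of the random intercept (long-range,
non-diminishing correlation), $S_i$ is the diagonal of marginal standard
deviations and $R_i$ is the subset of the full-grid correlation matrix at the
subject's times — which is how irregular schedules are handled: everything is
defined on the full grid, subjects pick out submatrices.

**Banded PACF regression.**  With Fisher's z-transform
$z(x) = \tfrac12\log\{(1+x)/(1-x)\}$ as link:

* stationary family: $z(\pi(t,t+j)) = (\gamma_0 + \gamma_1 j)\,1\{j \le a\}$,
  with $\gamma_1 \le 0$ so in-band partials decay with lag (a quadratic lag
  term is available behind a flag, default off);
* non-stationary family: $z(\pi(t,t+j)) = (g_{t0} + g_{t1} j)\,1\{j \le a\}$,
  where $g_{t0}, g_{t1}$ are smooth functions of time represented by low-rank
  thin-plate penalized splines and $g_{t1} \le 0$ at every grid point.

Setting $\pi = 0$ beyond lag $a$ *bands* the partial autocorrelation matrix.
The induced correlation matrix then has an $a$-banded precision matrix, and
all matrix inversions in the likelihood machinery stay at dimension
$\le a + 1$ regardless of $T$.

**Variance function.**  $\sigma^2(t) = \exp(\alpha_0 + \alpha_1 t/s_{var})$,
log-linear in time.  The time scaling $s_{var}$ is not pinned down by any
reference display; we default to $s_{var} = T$ (so $\alpha_1$ is the total
log-variance change across the grid, $O(1)$ for realistic decay) and expose it
as configuration.  A spline variance model is a straightforward extension we
deliberately did not include (the motivating data show a clean linear pattern
on the log scale).

**Indexing convention.**  Whether $g_{t0}, g_{t1}$ attach to the left
endpoint, right endpoint or midpoint of the pair $(t, t+j)$ is not determined
by the source material; we index by the **left endpoint** $t$ and document it
here.  Any of the three yields the same stationary special case.

## Algorithms

**PACF → correlation.**  The lag-recursive scheme fills
$\rho(t, t+j) = r_1' R_{mid}^{-1} r_3 + \pi(t,t+j) D_{t,t+j}$ lag by lag,
where $R_{mid}$ is the correlation of the intervening block and $D$ the
product of partial standard deviations.  For a band-$a$ PACF we use the
recursion only up to lag $a$ (inverting matrices of dimension $\le a - 1$) and
extend longer lags by the antedependence identity: regressing $Y_s$ on its $a$
immediate predecessors leaves innovations uncorrelated with the earlier past,
so $\rho(t, s) = \sum_{k=1}^{a} \phi_{s,k}\, \rho(t, s-k)$ for $s - t > a$.
The dense recursion (all lags) is retained in the code path and in the test
oracles; both agree to machine precision.

**Banded precision.**  $R^{-1} = U' D^{-1} U$ with $U$ unit lower triangular
holding the negated one-step regression coefficients (band $a$) and $D$ the
innovation variances; $\log|R| = \sum_t \log \delta_t$.  The factorization
makes the precision *exactly* $a$-banded by construction.

**Thin-plate basis.**  For scaled time $u = t/s$, fixed columns $(1, u)$ and
radial columns $|u - \nu_k/s|^3$ at $K$ knots; penalty
$\Omega_{lk} = |\nu_l/s - \nu_k/s|^3$.  Default knots follow the reference
layout: $K = 10$ knots at $s\,k/K$ with $s = \mathrm{round}(0.9\,T)$, which for
$T = 56$ reproduces knots at $5, 10, \dots, 50$ with scale 50.  A subtlety the
standard presentation glosses over: $\Omega$ has zero diagonal, hence zero
trace, hence is **indefinite** for $K \ge 2$ — no real $\Omega^{-1/2}$ exists.
We use the magnitude-eigenvalue root
$\Omega^{-1/2} := V\,|\Lambda|^{-1/2}V'$, the established practice for this
basis; the exact identity $Z\,\mathrm{sgn}(\Omega)\,Z' = T_2\,\Omega^{-1}T_2'$
holds for the resulting random design $Z$ and is what the tests assert.  The
reparameterized coefficients $\xi$ then carry independent
$N(0, \sigma_\gamma^2)$ priors, with $\sigma_\gamma$ acting as the smoothing
parameter.

## Mean structures and informative dropout

The mean is a linear model with intercept, time slope, a 0/1 dose indicator
and a dose-by-time interaction; time enters as $(t-1)/s_t$ with $s_t = 13$ by
default (per-year slopes on a 4-week grid; $t = 1$ is enrollment).  Under the
**conditional linear model** (CLM) each coefficient is linear in the
subject's observed dropout time: $\beta_k(d) = \theta_{k0} + \theta_{k1} d^*$
with $d^* = (d - \bar d)/s_d$, $\bar d$ the sample mean of observed dropout
times and $s_d = 100$ by default (for dropout recorded in weeks over a
multi-year study this keeps $|d^*|$ mostly inside $\pm 1.5$; the exact
rescaling is configuration, not hard-coded).  Marginal covariate effects are
recovered by averaging $\beta(d)$ over the dropout distribution, which is left
completely unspecified: per posterior draw and per dose group, Dirichlet
$(1,\dots,1)$ weights over that group's observed dropout times (Rubin's
Bayesian bootstrap).  The reported 4-vector is the reference-group marginal
intercept and slope plus the dose and dose-by-time contrasts.

The comparator is a random-intercept/random-slope LMM whose random-effect
covariance uses the modified Cholesky parameterization
$b_1 = \lambda b_0 + e$, guaranteeing a positive-definite $G$ from
unconstrained $(\lambda, \sigma_0, \sigma_e)$; residuals are independent
Gaussian — deliberately the simple comparator, with no serial term.

## Priors, sampler, and numerical choices

Priors: $N(0, 10^3)$ on all unconstrained location parameters
($\theta$, $\gamma$, fixed spline effects, $\alpha$, $\lambda$),
Uniform$(0, 20)$ on every SD ($\sigma_b$, $\sigma_0$, $\sigma_e$,
$\sigma_\epsilon$, smoothing SDs).  The constraint $\gamma_1 \le 0$ (and
$g_{t1} \le 0$ pointwise) is imposed by proposal rejection, not clamping.

The sampler is our own design (the original algorithm is not available):

* mean coefficients — conjugate Gaussian full conditional given the current
  covariance (random intercept integrated analytically, so no augmentation);
* covariance blocks — random-walk Metropolis per block
  ($\gamma$; spline fixed and random blocks; $\alpha$; $\sigma_b$; the LMM
  components), with step sizes adapted every 25 iterations **during burn-in
  only** toward 0.35 acceptance and frozen afterwards, preserving detailed
  balance for the retained draws.  In addition to the scalar-scale blocks,
  one **joint block** proposes all non-spline covariance parameters together
  using a proposal covariance learned from the burn-in draws (Haario-style,
  scaled by $2.38/\sqrt{d}$, likewise frozen after burn-in): the posterior
  has a pronounced ridge — slowly decaying serial correlation can mimic the
  random intercept, so $\gamma_0$, $\gamma_1$, $\alpha_0$ and $\sigma_b$ are
  strongly correlated (we observed $\mathrm{cor}(\gamma_0,\gamma_1) \approx
  -0.98$) — and independent scalar walks cross it very slowly, while the
  adapted joint proposal moves along it;
* smoothing SDs — exact conjugate draw: $\sigma_\gamma^2\mid\xi$ is
  inverse-gamma$((K-1)/2, \sum\xi_k^2/2)$ truncated to the uniform prior
  support, sampled by inverse CDF.  A floor of $\sigma_\gamma \ge 0.01$
  prevents the absorbing state at 0 (with all $\xi \approx 0$ the conditional
  collapses and would freeze the spline block permanently).

Degenerate and boundary cases: proposals whose PACF evaluates within
$10^{-12}$ of $\pm 1$, or whose subject covariance fails its Cholesky, get
log-likelihood $-\infty$ and are rejected; initialization uses OLS for the
mean, a log-variance regression and lag-1 residual correlation for the
covariance, with up to 10 shrinking retries if the likelihood diverges.
Chains beyond the first get jittered starts.  All randomness flows through R's
RNG from the user seed, so identical seeds give bit-identical chains.

Model comparison uses DIC on the **marginal** likelihood (random effects
integrated out): $\bar D$ is the posterior mean deviance over stored draws,
$\hat D$ the deviance at posterior means, $p_D = \bar D - \hat D$,
$DIC = \bar D + p_D$.  Band count $a$ is chosen by minimizing DIC over a
candidate grid (the `dic` CLI subcommand mirrors this workflow).

The $\chi^2$ posterior predictive check replicates the *observed-data*
structure per posterior draw: replicated dropout times from the empirical
dropout distribution, replicated schedules by resampling the pooled empirical
gap times from enrollment until dropout (gaps pooled across subjects, not
stratified — the simplest reading of "the empirical distribution of the gap
times"), dose labels reused (dose is a design variable), responses simulated
from the current parameters, and the discrepancy
$\sum_i (y_i - \mu_i)' \Sigma_i^{-1} (y_i - \mu_i)$ computed with random
effects integrated out.  Subjects are processed in sorted-id order so the
p-value is reproducible regardless of row order.

## The synthetic worlds, and what a green test establishes

No real data ship with the package.  The generator
(`sim_scenario()` / `simulate_dataset()`) draws, per subject: a dose, a
dropout time, a schedule (enrollment plus resampled gaps up to dropout on a
4-week grid), and one multivariate normal vector with the model's mean and
covariance.  Three stated worlds (`make_benchmark_scenarios()`):

1. **stationary_recovery** — N = 300, T = 20, band 2, $\gamma = (1.2, -0.25)$,
   $\alpha = (4.65, -1.76)$, $\sigma_b = 8$, CLM coefficients at
   CD4-scale magnitudes.  Two deliberate choices: the dropout centering
   constant is set to the *realized* sample mean of the simulated dropout
   times, so the fitted CLM (which centers at the observed sample mean)
   targets exactly the generating $\theta$; and $\gamma$ was chosen so that
   the z-line does **not** extrapolate to zero at lag $a+1$ — with
   $\gamma = (1.2, -0.4)$ the stationary families with $a = 2$ and $a = 3$
   are observationally equivalent and band selection is ill-posed.
2. **nonstationary_decay** — $g_{t0}$ decreasing from ≈1.5 to ≈0.4 across the
   grid, $g_{t1} \equiv -0.3$: higher, slower-decaying correlation early in
   follow-up.
3. **informative_dropout** — dropout depends on the latent random intercept
   through a logistic link (low intercept → early dropout), emulating the
   qualitative pattern seen in long-term trials; the dependence is ignorable
   given the model, so likelihood fits remain valid.

What the generator does *not* emulate: skewed or heavy-tailed outcomes,
measurement-time processes that depend on past *outcomes* rather than latent
effects, missingness that is not ignorable, and post-dropout mean changes.  A
green parameter-recovery or PPC test therefore establishes internal
consistency of model, likelihood and sampler — not robustness to those
violations.

## Reduced test sizes and stochastic criteria

The acceptance suite runs full-size where stated (N = 300, T = 20, 4000
iterations after 1000 burn-in) and reduced replicate studies elsewhere,
chosen once for a 1-CPU budget: interval-coverage replicates at
N = 100/T = 12 (single chain, 500 kept), DIC band-selection replicates at
N = 150/T = 15, PPC calibration replicates at N = 80/T = 12.  The
"all parameters within 3 posterior SDs" recovery check is a stochastic event
with a non-trivial failure probability even for a perfectly calibrated
posterior (13 parameters, two of them near-collinear dropout modifiers), so
it is asserted over three independent datasets requiring at least two full
passes, at the unmodified 3-SD tolerance.

## Known limitations

* The mean CLM assumes the pre-dropout slope continues after dropout; that
  assumption is not identifiable from observed data, and no sensitivity
  analysis is included.
* Categorical/count outcomes (latent Gaussian process link) are out of scope.
* The band count is selected by DIC, not given a prior.
* Full-grid conversion cost grows as $O(T^2 a)$ with the banded path; very
  fine grids (hundreds of points) are feasible but not optimized further
  (no parallelization).
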