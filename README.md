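# pacfcov

Bayesian covariance modeling for **irregular continuous longitudinal data**
through the partial autocorrelation function (PACF), with conditional linear
models in the observed dropout time for informative dropout.

## The problem and who this is for

In long-term follow-up studies (the motivating setting is repeated biomarker
measurements in a multi-year clinical trial), subjects are measured at
irregular, subject-specific times and often drop out for outcome-related
reasons.  In settings with outcome-dependent follow-up or ignorable
missingness, *valid mean inference requires a correctly specified covariance
function* — and a covariance function must be positive definite, which makes
flexible modeling hard on the correlation scale.

`pacfcov` is for biostatisticians who need flexible, guaranteed-valid
covariance models for such data.  It parameterizes the correlation structure
by the **partial autocorrelations**
π(t, t+j) = Cor{Y(t), Y(t+j) | Y(t+1), …, Y(t+j−1)} on a discrete grid
t = 1, …, T.  Each π can vary freely in (−1, 1): positive definiteness is
automatic.  Setting π = 0 beyond lag *a* ("banding") gives an *a*-banded
precision matrix and means no matrix larger than (a+1)×(a+1) is ever
inverted, whatever T is.

The model, in the field's standard notation:

- covariance: Σᵢ = σ_b² J + Sᵢ Rᵢ Sᵢ (random intercept + serial part),
  with σ²(t) = exp(α₀ + α₁ t/s) and Rᵢ induced by the PACF model;
- stationary PACF regression: z(π(t, t+j)) = (γ₀ + γ₁ j)·1{j ≤ a}, with
  Fisher's z-link and γ₁ ≤ 0;
- non-stationary PACF regression: z(π(t, t+j)) = (g_t0 + g_t1 j)·1{j ≤ a},
  where g_t0, g_t1 are penalized low-rank thin-plate splines in t with
  g_t1 ≤ 0;
- mean (conditional linear model): μᵢ(t) = β₀(dᵢ) + β₁(dᵢ)(t−1)/13 +
  β₂(dᵢ)doseᵢ + β₃(dᵢ)doseᵢ(t−1)/13, with β_k(d) = θ_k0 + θ_k1 d*
  linear in the rescaled observed dropout time — marginal effects recovered
  by Bayesian-bootstrap averaging over the empirical dropout distribution.

Inference is MCMC (conjugate Gaussian mean updates; adaptive random-walk
Metropolis for covariance blocks, including a joint adaptive-covariance block
for the strongly correlated serial/variance/random-intercept parameters);
band selection uses DIC on the marginal likelihood; model adequacy uses a χ²
posterior predictive check with replicated dropout times and gap-resampled
measurement schedules.  An RI+RS linear mixed model with modified-Cholesky
random-effect covariance is included as the comparator.

## Worked example

Simulate the benchmark world (N = 300 subjects, T = 20 grid points at 4-week
resolution, band-2 stationary truth with γ = (1.2, −0.25),
α = (4.65, −1.76), σ_b = 8, CLM mean, irregular gaps, categorical dropout),
fit the matching model, and summarize:

```r
library(pacfcov)

scenario <- make_benchmark_scenarios()$stationary_recovery
dat <- simulate_dataset(scenario, seed = 42)
head(as.data.frame(dat), 4)
#>   id time gridtime        y dose dropout
#> 1  1    4        1 52.36295    1      76
#> 2  1    8        2 44.36466    1      76
#> 3  1   12        3 46.98976    1      76
#> 4  1   20        5 41.76835    1      76

fit <- run_mcmc(dat, pacf_model("stationary", a = 2, mean = "clm"),
                iterations = 4000, burn_in = 1000, chains = 2, seed = 1)
summ <- posterior_summary(fit)
summ[summ$parameter %in% c("gamma0","gamma1","alpha0","alpha1","sigma_b"),
     c("parameter","median","lower95","upper95","rhat")]
#>  parameter median lower95 upper95 rhat
#>     gamma0  1.398   1.107   1.750    1
#>     gamma1 -0.386  -0.567  -0.232    1
#>     alpha0  4.620   4.381   4.881    1
#>     alpha1 -1.567  -1.816  -1.315    1
#>    sigma_b  7.745   6.437   8.923    1
```

Every 95% interval covers its generating value: γ₀ = 1.2, γ₁ = −0.25
(z-scale level and decay of the in-band partials), α₀ = 4.65, α₁ = −1.76
(log variance ≈ 105 at enrollment decaying to ≈ 18), σ_b = 8 (large
between-subject heterogeneity).  Split-R̂ ≈ 1 says the two chains agree.

```r
compute_dic(fit, dat)
#> Dbar = 14529.6, Dhat = 14516.8, pD = 12.8, DIC = 14542.4

ppc_chi2(fit, dat, n_draws = 100, seed = 1)
#> posterior predictive check: ppp = 0.810 (100 draws)

marginal_effects(fit, dat, seed = 1)
#> Marginal covariate effects (Bayesian bootstrap over dropout times)
#>       effect median lower95 upper95
#> 1  intercept 30.463   28.51   32.36
#> 2      slope -5.123   -7.12   -3.24
#> 3       dose -0.488   -3.22    2.23
#> 4 dose_slope -0.581   -3.32    2.12
```

pD ≈ 13 matches the 13 free parameters of this model; ppp = 0.81 (well
inside (0.05, 0.95)) gives no evidence of lack of fit; the marginal slope
−5.1 per year is the bootstrap average of β₁(dᵢ) over the reference group's
dropout distribution (the generating marginal slope is θ₁₀ = −4.8).

To compare band counts as in a real analysis, use the CLI:

```sh
Rscript -e 'pacfcov::pacfcov_cli()' dic --data dat.csv --config model.cfg \
    --bands 1,2,3,4 --iterations 1000 --burn-in 500 --seed 1 --out dic.csv
```

which prints a table with `band, Dbar, Dhat, pD, DIC` rows (smallest DIC
wins).  `simulate`, `fit`, `ppc` and `effects` subcommands complete the
pipeline; an executable front end is installed at `inst/cli/pacfcov`.

## Package layout

- `R/pacf_core.R` — PACF ↔ correlation algebra, banded precision
- `R/covariance_model.R` — thin-plate basis, PACF/variance regression models
- `R/mean_model.R` — CLM and LMM mean structures
- `R/bayes_fit.R` — likelihood, priors, MCMC, DIC, diagnostics
- `R/postfit.R` — Bayesian-bootstrap marginal effects, χ² PPC
- `R/synthetic.R` — scenario generator and benchmark worlds
- `R/interface.R`, `R/cli.R` — long-format CSV I/O, discretization, CLI
- `src/pacfcov.cpp` — compiled kernels (conversion recursion, banded
  factorization, subject-level Gaussian likelihood)
- `vignettes/pacf-covariance-models.Rmd` — the methods vignette: model,
  assumptions, sampler design, numerical choices, what the synthetic worlds
  do and do not establish
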