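// Core numerical kernels: PACF -> correlation recursion, banded precision via
// the antedependence (modified Cholesky) factorization, and per-subject
// Gaussian marginal log-likelihood / quadratic-form accumulators.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Lag-recursive conversion of a (banded) partial autocorrelation matrix to the
// marginal correlation matrix.  Pi is T x T symmetric with Pi(t, t+j) holding
// the lag-j partial autocorrelation (0 beyond the band); the diagonal is
// ignored.  For lag j >= 2,
//   rho(t, t+j) = r1' R_mid^{-1} r3 + pi(t, t+j) * D,
// with R_mid the correlation of the intervening values, r1/r3 the correlations
// of the endpoints with them, and D the product of partial standard deviations.
// [[Rcpp::export]]
arma::mat pacf_to_corr_cpp(const arma::mat& Pi, const int band = -1) {
  const uword T = Pi.n_rows;
  mat R(T, T, fill::eye);
  if (T < 2) return R;
  for (uword t = 0; t + 1 < T; ++t) {
    R(t, t + 1) = Pi(t, t + 1);
    R(t + 1, t) = Pi(t, t + 1);
  }
  // jmax: largest lag that must go through the full recursion.  When the PACF
  // is known to be band-limited, longer-lag correlations follow from the
  // antedependence linear recursion below, which needs no matrix inversions.
  const uword jmax = (band >= 1 && (uword)band < T) ? (uword)band : T - 1;
  for (uword j = 2; j <= jmax; ++j) {
    for (uword t = 0; t + j < T; ++t) {
      uvec mid = regspace<uvec>(t + 1, t + j - 1);
      mat Rm = R.submat(mid, mid);
      vec r1(j - 1), r3(j - 1);
      for (uword k = 0; k < j - 1; ++k) {
        r1(k) = R(t, t + 1 + k);
        r3(k) = R(t + j, t + 1 + k);
      }
      vec s1 = solve(Rm, r1, solve_opts::likely_sympd);
      vec s3 = solve(Rm, r3, solve_opts::likely_sympd);
      double d1 = 1.0 - dot(r1, s1);
      double d3 = 1.0 - dot(r3, s3);
      if (d1 < 0.0) d1 = 0.0;
      if (d3 < 0.0) d3 = 0.0;
      double rho = dot(r1, s3) + Pi(t, t + j) * std::sqrt(d1 * d3);
      R(t, t + j) = rho;
      R(t + j, t) = rho;
    }
  }
  if (jmax == T - 1) return R;
  // banded extension: for an order-a antedependence process the regression of
  // Y_t on its a immediate predecessors has innovations uncorrelated with the
  // earlier past, so rho(s, t) = sum_k phi_{t,k} rho(s, t - k) for t - s > a.
  const uword a = jmax;
  for (uword s = a + 1; s < T; ++s) {        // right endpoint
    uword p = std::min<uword>(s, a);
    uvec prev = regspace<uvec>(s - p, s - 1);
    mat Rp = R.submat(prev, prev);
    vec r(p);
    for (uword k = 0; k < p; ++k) r(k) = R(s - p + k, s);
    vec phi = solve(Rp, r, solve_opts::likely_sympd);
    for (uword t = s - p; t-- > 0; ) {       // lags beyond the band
      double rho = 0.0;
      for (uword k = 0; k < p; ++k) rho += phi(k) * R(t, s - p + k);
      R(t, s) = rho;
      R(s, t) = rho;
    }
  }
  return R;
}

// Precision matrix and log-determinant of a correlation matrix whose PACF is
// a-banded.  Uses the order-a antedependence factorization R^{-1} = U' D^{-1} U
// with U unit lower triangular (row t carries minus the coefficients of the
// regression of Y_t on its a immediate predecessors) and D the diagonal of
// innovation variances; only matrices of dimension <= a are inverted and the
// result is exactly a-banded by construction.
// [[Rcpp::export]]
Rcpp::List banded_precision_cpp(const arma::mat& R, const int a) {
  const uword T = R.n_rows;
  mat U(T, T, fill::zeros);
  U.diag().ones();
  vec delta(T);
  delta(0) = 1.0;
  for (uword t = 1; t < T; ++t) {
    uword p = std::min<uword>(t, (uword)a);
    if (p == 0) { delta(t) = 1.0; continue; }
    uvec prev = regspace<uvec>(t - p, t - 1);
    mat Rp = R.submat(prev, prev);
    vec r(p);
    for (uword k = 0; k < p; ++k) r(k) = R(t - p + k, t);
    vec phi = solve(Rp, r, solve_opts::likely_sympd);
    double d = 1.0 - dot(r, phi);
    if (d <= 0.0) Rcpp::stop("correlation matrix not positive definite at index %d", (int)(t + 1));
    delta(t) = d;
    for (uword k = 0; k < p; ++k) U(t, t - p + k) = -phi(k);
  }
  mat P = U.t() * diagmat(1.0 / delta) * U;
  double logdet = accu(log(delta));
  return Rcpp::List::create(Rcpp::Named("precision") = P,
                            Rcpp::Named("logdet") = logdet);
}

// Shared subject-covariance builder: Sigma_i(k,l) =
//   sigma_b^2 + sd(t_k) sd(t_l) R(t_k, t_l) + nugget * 1{k == l}.
static inline mat subject_sigma(const ivec& tidx, const uword s, const uword n,
                                const mat& R, const vec& sd,
                                const double sb2, const double nugget) {
  mat S(n, n);
  for (uword k = 0; k < n; ++k) {
    int tk = tidx(s + k);
    for (uword l = 0; l <= k; ++l) {
      int tl = tidx(s + l);
      double v = sb2 + sd(tk) * sd(tl) * R(tk, tl);
      S(k, l) = v;
      S(l, k) = v;
    }
    S(k, k) += nugget;
  }
  return S;
}

// Total Gaussian marginal log-likelihood over subjects, plus the chi-square
// discrepancy sum_i (y_i - mu_i)' Sigma_i^{-1} (y_i - mu_i).  Subjects are
// concatenated: start (0-based offsets, length N+1) indexes into y/mu/tidx;
// tidx holds 0-based grid indices.  Returns -Inf log-likelihood if any
// Sigma_i fails its Cholesky factorization.
// [[Rcpp::export]]
Rcpp::List gauss_profile_cpp(const arma::vec& y, const arma::vec& mu,
                             const arma::ivec& tidx, const arma::ivec& start,
                             const arma::mat& R, const arma::vec& sd,
                             const double sigma_b, const double nugget) {
  const uword N = start.n_elem - 1;
  const double sb2 = sigma_b * sigma_b;
  double ll = 0.0, chi2 = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (uword i = 0; i < N; ++i) {
    uword s = (uword)start(i), n = (uword)start(i + 1) - s;
    mat S = subject_sigma(tidx, s, n, R, sd, sb2, nugget);
    mat L;
    if (!chol(L, S, "lower")) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("chi2") = R_PosInf);
    }
    vec r = y.subvec(s, s + n - 1) - mu.subvec(s, s + n - 1);
    vec z = solve(trimatl(L), r);
    double q = dot(z, z);
    chi2 += q;
    ll += -0.5 * (n * l2pi + q) - accu(log(L.diag()));
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("chi2") = chi2);
}

// Accumulates sum_i X_i' Sigma_i^{-1} X_i and sum_i X_i' Sigma_i^{-1} y_i for
// the conjugate Gaussian update of the mean coefficients.  X is the row-bound
// design matrix over all observations.
// [[Rcpp::export]]
Rcpp::List xtsx_cpp(const arma::vec& y, const arma::mat& X,
                    const arma::ivec& tidx, const arma::ivec& start,
                    const arma::mat& R, const arma::vec& sd,
                    const double sigma_b, const double nugget) {
  const uword N = start.n_elem - 1, p = X.n_cols;
  const double sb2 = sigma_b * sigma_b;
  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    uword s = (uword)start(i), n = (uword)start(i + 1) - s;
    mat S = subject_sigma(tidx, s, n, R, sd, sb2, nugget);
    mat L;
    if (!chol(L, S, "lower"))
      Rcpp::stop("subject covariance not positive definite in mean update");
    mat Xi = X.rows(s, s + n - 1);
    mat Zx = solve(trimatl(L), Xi);
    vec Zy = solve(trimatl(L), y.subvec(s, s + n - 1));
    A += Zx.t() * Zx;
    b += Zx.t() * Zy;
  }
  return Rcpp::List::create(Rcpp::Named("XtSX") = A,
                            Rcpp::Named("XtSy") = b);
}
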