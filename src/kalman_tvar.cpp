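#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Kalman-filtered time-varying AR estimation for a K-channel series.
//
// Per sink channel i the state is the stacked coefficient vector
// a_i (length d = K * p, ordered source-major: source j lags 1..p), with a
// random-walk state model implemented as covariance inflation
// P <- P / (1 - c) (exponential forgetting); c -> 0 recovers the ordinary
// least-squares VAR solution, larger c tracks changes faster. Observation
// noise is tracked adaptively per sink. A tiny ridge keeps the innovation
// variance positive; usage is flagged.
//
// y: n x K data matrix; p: model order; c: adaptation rate in [0, 1).
// Returns coef: d x K x n cube (slice t, column i = sink i's coefficients),
// resid_var: per-sink final noise estimate, flagged: ridge engaged.
// [[Rcpp::export]]
Rcpp::List kalman_tvar_cpp(const arma::mat& y, int p, double c,
                           double ridge = 1e-9) {
  const int n = y.n_rows, K = y.n_cols, d = K * p;
  if (n <= 2 * d) Rcpp::stop("series too short for the requested order");
  if (c < 0.0 || c >= 1.0) Rcpp::stop("adaptation rate must be in [0, 1)");
  // common rescaling of all channels leaves AR coefficients unchanged but
  // keeps the recursion well conditioned
  const double scale = arma::stddev(arma::vectorise(y)) + 1e-300;
  const arma::mat ys = y / scale;
  const double trace_cap = 1e6 * d;
  arma::cube coef(d, K, n, arma::fill::zeros);
  arma::mat a(d, K, arma::fill::zeros);
  std::vector<arma::mat> P(K, arma::mat(d, d, arma::fill::eye));
  for (auto& Pi : P) Pi *= 100.0;
  arma::vec r(K, arma::fill::ones);
  const double lam = 1.0 - c;
  arma::vec h(d);
  bool flagged = false;
  for (int t = p; t < n; ++t) {
    int idx = 0;
    for (int j = 0; j < K; ++j)
      for (int m = 1; m <= p; ++m) h(idx++) = ys(t - m, j);
    for (int i = 0; i < K; ++i) {
      arma::mat Pp = P[i] / lam;
      arma::vec Ph = Pp * h;
      double s = arma::dot(h, Ph) + r(i);
      if (s < ridge) { s += ridge; flagged = true; }
      arma::vec k = Ph / s;
      double e = ys(t, i) - arma::dot(h, a.col(i));
      a.col(i) += k * e;
      Pp -= k * Ph.t();
      Pp = 0.5 * (Pp + Pp.t());              // keep symmetric / PSD-ish
      double tr = arma::trace(Pp);
      if (tr > trace_cap) { Pp *= trace_cap / tr; flagged = true; }
      P[i] = Pp;
      double cc = (c > 0.0) ? c : 1.0 / double(t - p + 2);
      r(i) = std::max((1.0 - cc) * r(i) + cc * e * e, 1e-10);
    }
    coef.slice(t) = a;
  }
  for (int t = 0; t < p; ++t) coef.slice(t) = coef.slice(p);
  return Rcpp::List::create(Rcpp::Named("coef") = coef,
                            Rcpp::Named("resid_var") = r * scale * scale,
                            Rcpp::Named("flagged") = flagged);
}
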