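// BayesB Gibbs sampler. Uses R's RNG (RNGScope) so chains are exactly
// reproducible under set.seed() from the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// scaled-inverse-chi-square draw: (df * scale) / chisq(df)
static inline double rsinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List bayesb_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                      const arma::mat& Mc, double pi_null,
                      int n_iter, int burn_in, int thin,
                      double nu, double S, bool keep_trace) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int m = Mc.n_cols;
  const bool nu_inf = (nu < 0);   // nu = Inf encoded as -1: variances fixed at S

  arma::vec xtx(p), mtm(m);
  for (int l = 0; l < p; ++l) xtx(l) = arma::dot(X.col(l), X.col(l));
  for (int j = 0; j < m; ++j) mtm(j) = arma::dot(Mc.col(j), Mc.col(j));

  arma::vec b(p, arma::fill::zeros);
  b(0) = arma::mean(y);
  arma::vec u(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  arma::vec su2(m); su2.fill(S);
  double se2 = arma::var(y) / 2.0;
  if (se2 <= 0) se2 = 1e-6;

  arma::vec e = y - X * b;   // u = 0 initially

  arma::vec b_sum(p, arma::fill::zeros), u_sum(m, arma::fill::zeros);
  arma::vec d_sum(m, arma::fill::zeros);
  double se2_sum = 0.0, gvar_sum = 0.0;
  int n_kept = 0;
  const double log_prior_odds =
      (pi_null <= 0.0) ? R_PosInf :
      (pi_null >= 1.0) ? R_NegInf : std::log((1.0 - pi_null) / pi_null);

  std::vector<double> tr_se2, tr_gvar;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int l = 0; l < p; ++l) {
      e += X.col(l) * b(l);
      double rhs = arma::dot(X.col(l), e);
      double mean = rhs / xtx(l);
      b(l) = R::rnorm(mean, std::sqrt(se2 / xtx(l)));
      e -= X.col(l) * b(l);
    }
    // marker effects
    for (int j = 0; j < m; ++j) {
      double c = mtm(j);
      if (c <= 0) { u(j) = 0; delta(j) = 0; continue; }
      if (delta(j)) e += Mc.col(j) * u(j);
      double rhs = arma::dot(Mc.col(j), e);
      int dj;
      if (log_prior_odds == R_PosInf) dj = 1;
      else if (log_prior_odds == R_NegInf) dj = 0;
      else {
        double v0 = c * se2;
        double v1 = c * c * su2(j) + c * se2;
        double logr = log_prior_odds + 0.5 * (std::log(v0) - std::log(v1)) +
                      0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p1 = 1.0 / (1.0 + std::exp(-logr));
        dj = (unif_rand() < p1) ? 1 : 0;
      }
      if (dj) {
        double prec = c + se2 / su2(j);
        double mean = rhs / prec;
        u(j) = R::rnorm(mean, std::sqrt(se2 / prec));
        e -= Mc.col(j) * u(j);
      } else {
        u(j) = 0.0;
      }
      delta(j) = dj;
      if (!nu_inf) {
        su2(j) = dj ? rsinvchisq(nu + 1.0, (nu * S + u(j) * u(j)) / (nu + 1.0))
                    : rsinvchisq(nu, S);
      }
    }
    // residual variance: flat scale prior, inverse-chi-square conditional
    se2 = arma::dot(e, e) / R::rchisq((double)(n - 2));
    if (!std::isfinite(se2) || se2 <= 0)
      stop("non-finite residual variance; check hyperparameter S");

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      b_sum += b; u_sum += u;
      for (int j = 0; j < m; ++j) d_sum(j) += delta(j);
      se2_sum += se2;
      arma::vec gv = y - X * b - e;   // = Mc * u
      double gvar = arma::var(gv);
      gvar_sum += gvar;
      ++n_kept;
      if (keep_trace) { tr_se2.push_back(se2); tr_gvar.push_back(gvar); }
    }
  }
  return List::create(
    _["b_mean"] = b_sum / n_kept,
    _["u_mean"] = u_sum / n_kept,
    _["delta_mean"] = d_sum / n_kept,
    _["sigma_e2_mean"] = se2_sum / n_kept,
    _["gvar_mean"] = gvar_sum / n_kept,
    _["n_kept"] = n_kept,
    _["trace_se2"] = tr_se2,
    _["trace_gvar"] = tr_gvar);
}
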