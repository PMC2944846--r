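// EM core for the latent class model: a finite mixture of K classes, each an
// independent multinomial over genotype categories {0,1,2} at every SNP.
// Missing entries contribute no factor to the likelihood (MAR marginalisation),
// so an all-missing individual has per-class log-density 0 and overall
// contribution log(sum_k pi_k) = 0.
//
// Data are passed as three n x m 0/1 indicator matrices (one per genotype
// category); a missing entry is 0 in all three. This makes both the E-step and
// the M-step plain matrix products, which is where almost all time goes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double row_logsumexp(const rowvec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(v - m)));
}

// Per-individual, per-class log p(x_i | class k) + log pi_k.
// theta_g: m x K matrices of category probabilities.
static mat weighted_logdens(const mat& I0, const mat& I1, const mat& I2,
                            const mat& th0, const mat& th1, const mat& th2,
                            const rowvec& logpi) {
  mat lp = I0 * log(th0) + I1 * log(th1) + I2 * log(th2);
  lp.each_row() += logpi;
  return lp;
}

// [[Rcpp::export]]
Rcpp::List cpp_em(const arma::mat& I0, const arma::mat& I1, const arma::mat& I2,
                  arma::mat resp, const double tol, const int max_iter,
                  const double eps) {
  const uword n = I0.n_rows, m = I0.n_cols;
  const uword K = resp.n_cols;

  rowvec pi(K);
  mat th0(m, K), th1(m, K), th2(m, K);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  double ll = -datum::inf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // M-step from current responsibilities
    pi = mean(resp, 0);
    mat c0 = I0.t() * resp;          // m x K observed-category mass
    mat c1 = I1.t() * resp;
    mat c2 = I2.t() * resp;
    mat denom = c0 + c1 + c2;        // responsibility mass observed at each SNP
    th0 = (c0 + eps) / (denom + 3.0 * eps);
    th1 = (c1 + eps) / (denom + 3.0 * eps);
    th2 = (c2 + eps) / (denom + 3.0 * eps);

    // E-step
    mat lp = weighted_logdens(I0, I1, I2, th0, th1, th2, log(pi));
    double ll_new = 0.0;
    for (uword i = 0; i < n; ++i) {
      double lse = row_logsumexp(lp.row(i));
      ll_new += lse;
      resp.row(i) = exp(lp.row(i) - lse);
    }
    ll_trace.push_back(ll_new);

    if (iter > 1) {
      double rel = std::abs(ll_new - ll) / (std::abs(ll) + 1e-300);
      if (rel < tol) { ll = ll_new; converged = true; break; }
    }
    ll = ll_new;
  }

  return Rcpp::List::create(
    Rcpp::Named("pi") = pi.t(),
    Rcpp::Named("theta0") = th0, Rcpp::Named("theta1") = th1,
    Rcpp::Named("theta2") = th2,
    Rcpp::Named("resp") = resp,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("ll_trace") = ll_trace,
    Rcpp::Named("n_iterations") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}

// Log-likelihood of a fixed model on data (no fitting); also returns the
// posterior responsibility matrix. theta matrices are m x K.
// [[Rcpp::export]]
Rcpp::List cpp_loglik(const arma::mat& I0, const arma::mat& I1, const arma::mat& I2,
                      const arma::vec& pi,
                      const arma::mat& th0, const arma::mat& th1,
                      const arma::mat& th2) {
  const uword n = I0.n_rows;
  mat lp = weighted_logdens(I0, I1, I2, th0, th1, th2, log(pi.t()));
  mat resp(n, pi.n_elem);
  vec row_ll(n);
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double lse = row_logsumexp(lp.row(i));
    row_ll(i) = lse;
    ll += lse;
    if (std::isfinite(lse)) {
      resp.row(i) = exp(lp.row(i) - lse);
    } else {
      resp.row(i).fill(datum::nan);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("row_loglik") = row_ll,
                            Rcpp::Named("resp") = resp);
}
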