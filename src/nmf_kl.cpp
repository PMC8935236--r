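// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Kullback-Leibler divergence D(X || WH) with the 0*log(0) = 0 convention.
static double kl_div(const arma::mat& X, const arma::mat& WH) {
  const arma::uword n = X.n_elem;
  const double* x = X.memptr();
  const double* wh = WH.memptr();
  double d = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double xi = x[i], whi = wh[i];
    if (xi > 0.0) d += xi * std::log(xi / whi) - xi + whi;
    else d += whi;
  }
  return d;
}

// Multiplicative updates for KL-divergence NMF (Brunet et al. variant).
// X (m x n) ~ W (m x r) H (r x n). W0/H0 supply the initialization; a small
// floor keeps entries strictly positive so the updates stay well defined.
// Returns W, H and the objective trace (initial objective first), stopping
// when the relative objective change drops below tol.
// When conn_stop > 0 the run additionally stops once the hard sample
// assignment (argmax over the columns of H) has been unchanged for
// conn_stop consecutive checks performed every check_every iterations --
// the connectivity-based stopping rule customary for consensus NMF, where
// the co-clustering pattern is the quantity of interest rather than the
// fully converged objective.
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
List nmf_kl_cpp(const arma::mat& X, const arma::mat& W0, const arma::mat& H0,
                int max_iter, double tol, int conn_stop = 0,
                int check_every = 10) {
  const double eps = 1e-12;
  arma::mat W = W0, H = H0;
  arma::mat WH = arma::clamp(W * H, eps, arma::datum::inf);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double obj = kl_div(X, WH);
  trace.push_back(obj);
  arma::urowvec labels(H.n_cols, arma::fill::zeros);
  int stable = 0;

  for (int it = 0; it < max_iter; ++it) {
    // H <- H * (W^T (X / WH)) / (W^T 1)
    arma::mat Q = X / WH;
    arma::vec wsum = arma::sum(W, 0).t();
    wsum = arma::clamp(wsum, eps, arma::datum::inf);
    H %= (W.t() * Q);
    H.each_col() /= wsum;
    H = arma::clamp(H, eps, arma::datum::inf);
    WH = arma::clamp(W * H, eps, arma::datum::inf);

    // W <- W * ((X / WH) H^T) / (1 H^T)
    Q = X / WH;
    arma::rowvec hsum = arma::sum(H, 1).t();
    hsum = arma::clamp(hsum, eps, arma::datum::inf);
    W %= (Q * H.t());
    W.each_row() /= hsum;
    W = arma::clamp(W, eps, arma::datum::inf);
    WH = arma::clamp(W * H, eps, arma::datum::inf);

    const double obj_new = kl_div(X, WH);
    trace.push_back(obj_new);
    const double rel = std::fabs(obj - obj_new) / std::max(std::fabs(obj), eps);
    obj = obj_new;
    if (rel < tol) break;
    if (conn_stop > 0 && ((it + 1) % check_every == 0)) {
      arma::urowvec lab_now = arma::index_max(H, 0);
      if (arma::all(lab_now == labels)) {
        if (++stable >= conn_stop) break;
      } else {
        stable = 0;
        labels = lab_now;
      }
    }
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
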