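// Sparse logistic point-process estimation: damped-Newton maximum likelihood
// on a fixed support, and a generalized orthogonal matching pursuit path that
// grows the support by the covariate with the largest partial log-likelihood
// gradient. Used by the Granger-causality module.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// overflow-safe log(1 + exp(eta))
static inline double ll_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double loglik_eta(const arma::vec& eta, const arma::vec& y) {
  double ll = 0.0;
  for (arma::uword t = 0; t < eta.n_elem; ++t)
    ll += y[t] * eta[t] - ll_log1pexp(eta[t]);
  return ll;
}

// Damped Newton ascent of the Bernoulli log-likelihood over columns `support`
// of X, with a small ridge guarding perfect separation. Returns beta on the
// support, the achieved log-likelihood, and a convergence flag.
static void newton_fit(const arma::mat& X, const arma::vec& y,
                       const arma::uvec& support, double ridge, double tol,
                       int maxit, arma::vec& beta, double& ll, bool& conv) {
  arma::mat Xs = X.cols(support);
  arma::uword p = Xs.n_cols;
  beta.zeros(p);
  arma::vec eta = Xs * beta;
  ll = loglik_eta(eta, y) - 0.5 * ridge * arma::dot(beta, beta);
  conv = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec grad = Xs.t() * (y - mu) - ridge * beta;
    if (arma::norm(grad, 2) < tol) { conv = true; break; }
    arma::vec w = mu % (1.0 - mu);
    arma::mat H = Xs.t() * (Xs.each_col() % w);
    H.diag() += ridge;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok) { H.diag() += 1e-8; arma::solve(step, H, grad); }
    // backtracking damping
    double s = 1.0;
    for (int half = 0; half < 30; ++half) {
      arma::vec cand = beta + s * step;
      arma::vec eta_c = Xs * cand;
      double ll_c = loglik_eta(eta_c, y) - 0.5 * ridge * arma::dot(cand, cand);
      if (ll_c >= ll - 1e-12) { beta = cand; eta = eta_c; ll = ll_c; break; }
      s *= 0.5;
    }
  }
  // report the un-penalized log-likelihood of the final fit
  ll = loglik_eta(eta, y);
}

// [[Rcpp::export]]
List cpp_newton_fit(const arma::mat& X, const arma::vec& y,
                    const arma::uvec& support0, double ridge, double tol,
                    int maxit) {
  arma::uvec support = support0;  // 0-based column indices
  arma::vec beta; double ll; bool conv;
  newton_fit(X, y, support, ridge, tol, maxit, beta, ll, conv);
  return List::create(_["beta"] = beta, _["loglik"] = ll,
                      _["converged"] = conv);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::mat& X, const arma::vec& y,
                  const arma::vec& beta_full) {
  arma::vec eta = X * beta_full;
  return loglik_eta(eta, y);
}

// OMP path: start from the always-kept columns (`keep`, 0-based; the
// baseline), then repeatedly add the not-yet-selected candidate column with
// the largest |partial gradient| and refit by Newton. `candidates` restricts
// which columns may enter. Returns, for every support size 0..max_add, the
// selected columns, coefficient vector (dense, length ncol(X)) and
// log-likelihood.
// [[Rcpp::export]]
List cpp_omp_path(const arma::mat& X, const arma::vec& y,
                  const arma::uvec& keep, const arma::uvec& candidates,
                  int max_add, double ridge, double tol, int maxit) {
  arma::uword P = X.n_cols;
  std::vector<arma::uword> sel(keep.begin(), keep.end());
  std::vector<bool> in(P, false);
  for (arma::uword j : keep) in[j] = true;
  int n_sizes = max_add + 1;
  List betas(n_sizes); NumericVector lls(n_sizes);
  List supports(n_sizes);
  arma::vec beta; double ll; bool conv;
  for (int size = 0; size <= max_add; ++size) {
    if (size > 0) {
      // gradient at current fit over all columns
      arma::uvec sup(sel);
      arma::vec dense(P, arma::fill::zeros);
      for (arma::uword k = 0; k < sup.n_elem; ++k) dense[sup[k]] = beta[k];
      arma::vec eta = X * dense;
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec g = X.t() * (y - mu);
      double best = -1.0; int best_j = -1;
      for (arma::uword c = 0; c < candidates.n_elem; ++c) {
        arma::uword j = candidates[c];
        if (in[j]) continue;
        double a = std::abs(g[j]);
        if (a > best) { best = a; best_j = (int)j; }
      }
      if (best_j < 0) {  // no candidates left: repeat previous fit
        betas[size] = betas[size - 1];
        lls[size] = lls[size - 1];
        supports[size] = supports[size - 1];
        continue;
      }
      sel.push_back((arma::uword)best_j);
      in[best_j] = true;
    }
    arma::uvec sup(sel);
    newton_fit(X, y, sup, ridge, tol, maxit, beta, ll, conv);
    arma::vec dense(P, arma::fill::zeros);
    for (arma::uword k = 0; k < sup.n_elem; ++k) dense[sup[k]] = beta[k];
    betas[size] = dense;
    lls[size] = ll;
    supports[size] = IntegerVector(sel.begin(), sel.end());
  }
  return List::create(_["beta"] = betas, _["loglik"] = lls,
                      _["support"] = supports);
}
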