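// Newton-Raphson logistic regression with a small ridge penalty and
// step-halving, plus a batched inner-cross-validation AUC routine used by
// the nested-CV subset search. X includes the intercept column; the penalty
// applies to all coefficients (negligible at the default lambda, exact ML
// at lambda = 0).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// penalized log-likelihood from eta and mu (log(1+exp(eta)) = -log(1-mu))
static inline double pen_ll_from_mu(const vec& y, const vec& eta,
                                    const vec& mu, const vec& beta,
                                    double lambda) {
  double ll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double om = 1.0 - mu(i);
    // log(1+exp(eta)) = -log(1-mu); for mu rounded to 1 it is ~eta
    double l1pe = (om > 0.0) ? -std::log(om) : (eta(i) > 0.0 ? eta(i) : 0.0);
    ll += y(i) * eta(i) - l1pe;
  }
  return ll - 0.5 * lambda * dot(beta, beta);
}

static inline void sigmoid(const vec& eta, vec& mu) {
  mu = 1.0 / (1.0 + exp(-eta));
}

// core fit; returns number of iterations, sets beta/eta/mu in place
static int newton_core(const mat& X, const vec& y, double lambda, double tol,
                       int max_iter, vec& beta, vec& eta, vec& mu,
                       bool& converged) {
  const uword p = X.n_cols;
  beta.zeros(p);
  eta.zeros(X.n_rows);
  sigmoid(eta, mu);
  double ll = pen_ll_from_mu(y, eta, mu, beta, lambda);
  converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    vec score = X.t() * (y - mu) - lambda * beta;
    if (abs(score).max() < tol) { converged = true; break; }
    vec w = mu % (1.0 - mu);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += lambda;
    vec step;
    if (!solve(step, H, score, solve_opts::likely_sympd + solve_opts::no_approx)) {
      step = pinv(H) * score;
    }
    vec new_beta = beta + step;
    vec new_eta = X * new_beta;
    vec new_mu(new_eta.n_elem);
    sigmoid(new_eta, new_mu);
    double new_ll = pen_ll_from_mu(y, new_eta, new_mu, new_beta, lambda);
    int halves = 0;
    while ((!std::isfinite(new_ll) || new_ll < ll) && halves < 30) {
      step *= 0.5;
      new_beta = beta + step;
      new_eta = X * new_beta;
      sigmoid(new_eta, new_mu);
      new_ll = pen_ll_from_mu(y, new_eta, new_mu, new_beta, lambda);
      ++halves;
    }
    beta = new_beta;
    eta = new_eta;
    mu = new_mu;
    double dll = new_ll - ll;
    ll = new_ll;
    // penalized log-likelihood stagnation: quasi-separated fits plateau long
    // before the score criterion is met; stop once progress is negligible
    if (std::fabs(dll) < 1e-10 * (1.0 + std::fabs(ll))) { converged = true; break; }
  }
  if (!converged) {
    vec score = X.t() * (y - mu) - lambda * beta;
    if (abs(score).max() < tol) converged = true;
  }
  return iter;
}

// [[Rcpp::export(name = ".logit_newton_cpp")]]
Rcpp::List logit_newton_cpp(const arma::mat& X, const arma::vec& y,
                            double lambda, double tol, int max_iter,
                            bool diagnostics = true) {
  vec beta, eta, mu;
  bool converged;
  int iter = newton_core(X, y, lambda, tol, max_iter, beta, eta, mu, converged);

  if (!diagnostics) {
    return Rcpp::List::create(Rcpp::Named("beta") = beta,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("iterations") = iter,
                              Rcpp::Named("fitted") = mu);
  }
  vec w = mu % (1.0 - mu);
  mat H = X.t() * (X.each_col() % w);
  H.diag() += lambda;
  double loglik = 0.0;
  for (uword i = 0; i < mu.n_elem; ++i) {
    double m = std::min(std::max(mu(i), 1e-300), 1.0 - 1e-16);
    loglik += y(i) * std::log(m) + (1.0 - y(i)) * std::log1p(-m);
  }
  mat V;
  if (!inv_sympd(V, H)) V = pinv(H);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("vcov") = V,
                            Rcpp::Named("fitted") = mu);
}

// AUC as the normalized Mann-Whitney statistic with midrank ties
static double auc_midrank(const vec& score, const ivec& y) {
  const uword n = score.n_elem;
  uvec ord = stable_sort_index(score);
  vec r(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && score(ord(j + 1)) == score(ord(i))) ++j;
    double mid = 0.5 * (i + j) + 1.0;  // average rank, 1-based
    for (uword t = i; t <= j; ++t) r(ord(t)) = mid;
    i = j + 1;
  }
  double P = 0.0, N = 0.0, rsum = 0.0;
  for (uword t = 0; t < n; ++t) {
    if (y(t) == 1) { P += 1.0; rsum += r(t); }
    else N += 1.0;
  }
  if (P == 0.0 || N == 0.0) return NA_REAL;
  return (rsum - P * (P + 1.0) / 2.0) / (P * N);
}

// For one outer-training set: run K-fold inner CV for every candidate
// column subset and return the subsets x folds AUC matrix. Features are
// standardized on each inner-training set (sd with n-1 denominator, matching
// the R path); a constant column gets sd 1.
// [[Rcpp::export(name = ".inner_cv_auc_cpp")]]
arma::mat inner_cv_auc_cpp(const arma::mat& X, const arma::ivec& y,
                           const Rcpp::List& subsets, const arma::ivec& fold,
                           int K, double lambda, double tol, int max_iter) {
  const uword nS = subsets.size();
  mat out(nS, K);
  vec yd = conv_to<vec>::from(y);

  for (int k = 1; k <= K; ++k) {
    uvec tr = find(fold != k);
    uvec te = find(fold == k);
    vec ytr = yd(tr);
    ivec yte = y(te);
    for (uword s = 0; s < nS; ++s) {
      uvec cols = Rcpp::as<arma::uvec>(subsets[s]);  // 0-based
      mat Xtr = X.submat(tr, cols);
      mat Xte = X.submat(te, cols);
      const uword m = cols.n_elem;
      rowvec ctr = mean(Xtr, 0);
      rowvec sc = stddev(Xtr, 0, 0);  // n-1 denominator
      for (uword j = 0; j < m; ++j) if (!(sc(j) > 0)) sc(j) = 1.0;
      Xtr.each_row() -= ctr; Xtr.each_row() /= sc;
      Xte.each_row() -= ctr; Xte.each_row() /= sc;
      mat Xtr1 = join_horiz(ones(Xtr.n_rows, 1), Xtr);
      vec beta, eta, mu;
      bool conv;
      newton_core(Xtr1, ytr, lambda, tol, max_iter, beta, eta, mu, conv);
      vec sc_te = beta(0) + Xte * beta.subvec(1, m);
      out(s, k - 1) = auc_midrank(sc_te, yte);
    }
  }
  return out;
}
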