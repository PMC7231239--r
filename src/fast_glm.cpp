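#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Logistic regression by iteratively reweighted least squares.
// Internal workhorse for the threshold scan and permutation loops, where
// tens of thousands of small fits are needed; user-facing model fits go
// through stats::glm.
//
// Returns coefficients, standard errors, log-likelihood and convergence flag.
// [[Rcpp::export(name = ".fast_logistic")]]
List fast_logistic(const arma::mat& X, const arma::vec& y,
                   int maxit = 30, double tol = 1e-9) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double ll_old = -std::numeric_limits<double>::infinity();
  double ll = ll_old;
  bool converged = false;

  arma::vec eta, mu, w, z;
  arma::mat XtWX(p, p);

  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    // clamp to keep weights and the working response finite under separation
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    w = mu % (1.0 - mu);
    z = eta + (y - mu) / w;

    const arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, X.t() * (w % z),
                          arma::solve_opts::likely_sympd);
    if (!ok) break;
    beta = beta_new;

    eta = X * beta;
    ll = arma::dot(y, eta) - arma::accu(arma::log1p(arma::exp(eta)));
    if (std::abs(ll - ll_old) < tol * (std::abs(ll) + 0.1)) {
      converged = true;
      break;
    }
    ll_old = ll;
  }

  // observed information at the solution for Wald standard errors
  eta = X * beta;
  mu = 1.0 / (1.0 + arma::exp(-eta));
  mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
  w = mu % (1.0 - mu);
  XtWX = X.t() * (X.each_col() % w);
  arma::mat cov;
  arma::vec se(p);
  if (arma::inv_sympd(cov, XtWX)) {
    se = arma::sqrt(cov.diag());
  } else {
    se.fill(NA_REAL);
  }

  return List::create(_["coef"] = beta, _["se"] = se,
                      _["loglik"] = ll, _["converged"] = converged);
}

// Log-likelihood of an intercept + offset-free logistic fit is not needed;
// the null model is fit with the same routine on the covariate columns.

// Fast ordinary least squares with residual sum of squares, used by the
// threshold scan for continuous outcomes.
// [[Rcpp::export(name = ".fast_ols")]]
List fast_ols(const arma::mat& X, const arma::vec& y) {
  arma::vec beta = arma::solve(X, y);
  const arma::vec resid = y - X * beta;
  const double rss = arma::dot(resid, resid);
  return List::create(_["coef"] = beta, _["rss"] = rss);
}
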