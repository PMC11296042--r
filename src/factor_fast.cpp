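// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Minres objective: sum of squared off-diagonal residuals of R - LL', with
// L the best rank-k factor matrix for the reduced correlation matrix
// R - diag(psi). Hot path of the uniqueness search.
// [[Rcpp::export]]
double minres_objective(const arma::vec& psi, const arma::mat& r, int k) {
  arma::mat rs = r;
  rs.diag() = 1.0 - psi;
  arma::vec ev;
  arma::mat v;
  if (!arma::eig_sym(ev, v, rs)) return 1e10;
  const int p = r.n_rows;
  arma::mat l(p, k, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    double lam = ev(p - 1 - j);
    if (lam > 0) l.col(j) = v.col(p - 1 - j) * std::sqrt(lam);
  }
  arma::mat resid = r - l * l.t();
  double f = 0.0;
  for (int i = 1; i < p; ++i)
    for (int j = 0; j < i; ++j) f += resid(i, j) * resid(i, j);
  return f;
}

// Oblique gradient-projection rotation with the quartimin criterion.
// Returns the rotated pattern matrix, factor correlations, rotation and
// criterion value for one start.
// [[Rcpp::export]]
List gpf_oblq_quartimin(const arma::mat& a, const arma::mat& tmat0,
                        int maxit, double eps) {
  const int k = a.n_cols;
  arma::mat nmat(k, k, arma::fill::ones);
  nmat.diag().zeros();

  arma::mat tmat = tmat0;
  arma::mat l = a * arma::inv(tmat).t();
  arma::mat l2 = arma::square(l);
  arma::mat gq = l % (l2 * nmat);
  double f = arma::accu(l2 % (l2 * nmat)) / 4.0;
  arma::mat g = -(l.t() * gq * arma::inv(tmat)).t();
  double al = 1.0;

  arma::mat tmat_t = tmat;
  for (int iter = 0; iter < maxit; ++iter) {
    arma::rowvec tg = arma::sum(tmat % g, 0);
    arma::mat gp = g - tmat * arma::diagmat(tg);
    double s = std::sqrt(arma::accu(arma::square(gp)));
    if (s < eps) break;
    al *= 2.0;
    double ft = f;
    for (int i = 0; i <= 20; ++i) {
      arma::mat x = tmat - al * gp;
      arma::rowvec v = 1.0 / arma::sqrt(arma::sum(arma::square(x), 0));
      tmat_t = x * arma::diagmat(v);
      l = a * arma::inv(tmat_t).t();
      l2 = arma::square(l);
      ft = arma::accu(l2 % (l2 * nmat)) / 4.0;
      if (ft < f - 0.5 * s * s * al) break;
      al /= 2.0;
    }
    tmat = tmat_t;
    f = ft;
    gq = l % (l2 * nmat);
    g = -(l.t() * gq * arma::inv(tmat)).t();
  }
  return List::create(_["loadings"] = l, _["phi"] = tmat.t() * tmat,
                      _["rotation"] = tmat, _["f"] = f);
}
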