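// Cross-validated LS-SVR mean squared error, the hot path of the swarm's
// fitness function. The bordered dual system is solved per fold through
// the Schur complement of the SPD block A = K_tr + I/gamma (see R/lssvr.R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double cvMSEImpl(const arma::mat& K, const arma::vec& y,
                        double gamma, const Rcpp::List& folds) {
  const arma::uword n = K.n_rows;
  const int nf = folds.size();
  arma::vec errs(nf);
  for (int f = 0; f < nf; ++f) {
    arma::uvec te = Rcpp::as<arma::uvec>(folds[f]);  // 0-based indices
    std::vector<char> isTe(n, 0);
    for (arma::uword i = 0; i < te.n_elem; ++i) isTe[te[i]] = 1;
    arma::uvec tr(n - te.n_elem);
    arma::uword k = 0;
    for (arma::uword i = 0; i < n; ++i) if (!isTe[i]) tr[k++] = i;

    arma::mat A = K.submat(tr, tr);
    A.diag() += 1.0 / gamma;
    arma::mat rhs(tr.n_elem, 2);
    rhs.col(0).ones();
    rhs.col(1) = y.elem(tr);
    arma::mat Z;
    bool ok = arma::solve(Z, A, rhs, arma::solve_opts::likely_sympd);
    if (!ok) Rcpp::stop("singular LS-SVR system in CV fold");
    double b = arma::accu(Z.col(1)) / arma::accu(Z.col(0));
    arma::vec alpha = Z.col(1) - b * Z.col(0);
    arma::vec pred = K.submat(te, tr) * alpha + b;
    arma::vec res = y.elem(te) - pred;
    errs[f] = arma::dot(res, res) / te.n_elem;
  }
  return arma::mean(errs);
}

// [[Rcpp::export]]
double cvMSEKernelCpp(const arma::mat& K, const arma::vec& y, double gamma,
                      const Rcpp::List& folds) {
  return cvMSEImpl(K, y, gamma, folds);
}

// Build the RBF kernel of a feature subset and run the CV fold loop in
// one pass (avoids materializing intermediates at the R level).
// [[Rcpp::export]]
double cvMSESubsetCpp(const arma::mat& X, const arma::vec& y,
                      double sigma2, double gamma,
                      const Rcpp::List& folds) {
  arma::vec sq = arma::sum(arma::square(X), 1);
  arma::mat K = -2.0 * (X * X.t());
  K.each_col() += sq;
  K.each_row() += sq.t();
  K.transform([sigma2](double d) {
    return std::exp(-(d > 0.0 ? d : 0.0) / sigma2);
  });
  return cvMSEImpl(K, y, gamma, folds);
}
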