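// Blockwise coordinate-descent graphical lasso with an elementwise penalty
// matrix. Solves max log det(Theta) - tr(S Theta) - sum_{a!=b} Rho_ab
// |Theta_ab| for small dense windows of peaks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::vec lasso_cd_cpp(const arma::mat& W11, const arma::vec& s12,
                              const arma::vec& rho, arma::vec beta,
                              int maxit, double tol) {
  const int p = s12.n_elem;
  arma::vec d = W11.diag();
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int k = 0; k < p; ++k) {
      double r = s12[k] - arma::dot(W11.col(k), beta) + d[k] * beta[k];
      double ar = std::abs(r) - rho[k];
      double b = (ar > 0.0) ? ((r > 0 ? ar : -ar) / d[k]) : 0.0;
      double ch = std::abs(b - beta[k]);
      if (ch > dmax) dmax = ch;
      beta[k] = b;
    }
    if (dmax < tol) break;
  }
  return beta;
}

// [[Rcpp::export]]
arma::mat glasso_fit_cpp(const arma::mat& S, const arma::mat& Rho,
                         int maxit, double tol) {
  const int p = S.n_cols;
  arma::mat W = S;
  arma::mat B(p - 1, p, arma::fill::zeros);
  double scale_ref = 0.0;
  int cnt = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { scale_ref += std::abs(S(i, j)); ++cnt; }
  scale_ref = (cnt ? scale_ref / cnt : 0.0) + 1e-12;

  for (int it = 0; it < maxit; ++it) {
    arma::mat W_old = W;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx(p - 1);
      int c = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[c++] = i;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec sj = S.col(j), rj = Rho.col(j);
      arma::vec beta = lasso_cd_cpp(W11, sj.elem(idx), rj.elem(idx),
                                    B.col(j), 200, 1e-7);
      B.col(j) = beta;
      arma::vec w12 = W11 * beta;
      for (int c2 = 0; c2 < p - 1; ++c2) {
        W(idx[c2], j) = w12[c2];
        W(j, idx[c2]) = w12[c2];
      }
    }
    if (arma::accu(arma::abs(W - W_old)) / (p * p) < tol * scale_ref) break;
  }

  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    int c = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx[c++] = i;
    arma::vec wj = W.col(j);
    double denom = W(j, j) - arma::dot(wj.elem(idx), B.col(j));
    if (!std::isfinite(denom) || denom <= 0.0)
      Rcpp::stop("penalized covariance is numerically singular; "
                 "raise the penalty scale lambda0");
    Theta(j, j) = 1.0 / denom;
    for (int c2 = 0; c2 < p - 1; ++c2)
      Theta(idx[c2], j) = -B(c2, j) / denom;
  }
  Theta = (Theta + Theta.t()) / 2.0;
  if (!Theta.is_finite())
    Rcpp::stop("non-finite precision estimate; raise the penalty "
               "scale lambda0");
  return Theta;
}
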