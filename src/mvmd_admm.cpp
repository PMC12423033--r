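// ADMM iteration loop of the multivariate variational mode decomposition.
// Operates on the nonnegative half-spectrum; the FFTs, mirror extension and
// initialization live on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".mvmd_admm_core")]]
Rcpp::List mvmd_admm_core(const arma::cx_mat& xhat_plus, // C x F spectra
                          const arma::vec& freq_axis,   // F normalized freqs
                          arma::vec omega,              // K initial centers
                          const double alpha, const double tau,
                          const double tol, const int max_iter,
                          const bool pin_first) {
  const uword C = xhat_plus.n_rows;
  const uword F = xhat_plus.n_cols;
  const uword K = omega.n_elem;
  const double eps = datum::eps;

  field<cx_mat> u(K);
  for (uword k = 0; k < K; ++k) u(k) = cx_mat(C, F, fill::zeros);
  cx_mat lambda(C, F, fill::zeros);
  cx_mat sum_u(C, F, fill::zeros);

  int iter = 0;
  double udiff = datum::inf;
  const rowvec f_row = freq_axis.t();

  while (iter < max_iter && udiff > tol) {
    udiff = 0.0;
    for (uword k = 0; k < K; ++k) {
      cx_mat& uk = u(k);
      sum_u -= uk; // leaves the sum over the other modes
      const rowvec recip =
          1.0 / (1.0 + 2.0 * alpha * square(f_row - omega(k)));
      cx_mat newu = xhat_plus - sum_u + lambda / 2.0;
      double num = 0.0, den = 0.0, d_old = 0.0, d_chg = 0.0;
      for (uword j = 0; j < F; ++j) {
        newu.col(j) *= recip(j);
        for (uword c = 0; c < C; ++c) {
          const double p = std::norm(newu(c, j));
          den += p;
          num += p * f_row(j);
          d_old += std::norm(uk(c, j));
          d_chg += std::norm(newu(c, j) - uk(c, j));
        }
      }
      if (den > 0.0 && !(pin_first && k == 0)) omega(k) = num / den;
      udiff += d_chg / (d_old + eps);
      uk = std::move(newu);
      sum_u += uk;
    }
    if (tau > 0.0) lambda += tau * (xhat_plus - sum_u);
    ++iter;
    if (!std::isfinite(udiff) || omega.has_nan()) {
      Rcpp::stop("solver diverged (non-finite spectra) at iteration %d", iter);
    }
  }

  Rcpp::List modes(K);
  for (uword k = 0; k < K; ++k) modes[k] = Rcpp::wrap(u(k));
  return Rcpp::List::create(
    Rcpp::Named("mode_spectra") = modes,
    Rcpp::Named("omega") = omega,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = udiff <= tol);
}
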