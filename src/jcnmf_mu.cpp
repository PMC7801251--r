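// Multiplicative-update inner loop for the joint-correlation NMF.
// Initialization and restart logic stay in R; this only iterates the
// KKT updates and records the objective each iteration.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// hard = 0: two coupled (or independent, lam = 0) factorizations with the
// soft Gram penalty toward R; hard = 1: a single shared W on both datasets.
// [[Rcpp::export]]
Rcpp::List jcnmf_mu(const arma::mat& X1, const arma::mat& X2,
                    arma::mat W1, arma::mat H1,
                    arma::mat W2, arma::mat H2,
                    const arma::mat& R, double lam, int hard,
                    int max_iter, double tol, double eps) {
  vec trace(max_iter, fill::zeros);
  bool converged = false;
  int n_iter = 0;
  double prev = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    if (hard) {
      H1 %= (W1.t() * X1) / ((W1.t() * W1) * H1 + eps);
      H2 %= (W1.t() * X2) / ((W1.t() * W1) * H2 + eps);
      W1 %= (X1 * H1.t() + X2 * H2.t()) /
            (W1 * (H1 * H1.t() + H2 * H2.t()) + eps);
      W2 = W1;
    } else {
      H1 %= (W1.t() * X1) / ((W1.t() * W1) * H1 + eps);
      H2 %= (W2.t() * X2) / ((W2.t() * W2) * H2 + eps);
      if (lam > 0) {
        W1 %= (X1 * H1.t() + 2 * lam * R * W1) /
              (W1 * (H1 * H1.t()) + 2 * lam * W1 * (W1.t() * W1) + eps);
        W2 %= (X2 * H2.t() + 2 * lam * R * W2) /
              (W2 * (H2 * H2.t()) + 2 * lam * W2 * (W2.t() * W2) + eps);
      } else {
        W1 %= (X1 * H1.t()) / (W1 * (H1 * H1.t()) + eps);
        W2 %= (X2 * H2.t()) / (W2 * (H2 * H2.t()) + eps);
      }
    }

    double obj = accu(square(X1 - W1 * H1)) + accu(square(X2 - W2 * H2));
    if (lam > 0) {
      obj += lam * (accu(square(W1 * W1.t() - R)) +
                    accu(square(W2 * W2.t() - R)));
    }
    trace(it) = obj;
    n_iter = it + 1;
    if (std::isfinite(prev) && std::fabs(prev - obj) <= tol * std::max(prev, eps)) {
      converged = true;
      break;
    }
    prev = obj;
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("H1") = H1,
      Rcpp::Named("W2") = W2, Rcpp::Named("H2") = H2,
      Rcpp::Named("objective_trace") = trace.head(n_iter),
      Rcpp::Named("n_iter") = n_iter,
      Rcpp::Named("converged") = converged);
}
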