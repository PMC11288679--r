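#include <Rcpp.h>
using namespace Rcpp;

// Multiplicative-update fit of the symmetric nonnegative factorisation
// A ~ X diag(lambda) X^T, minimising KL divergence D(A || X L X^T).
// A is the weight matrix normalised to total 1 (sum over all entries).
// Columns of X are kept on the simplex (sum 1), as is lambda, so the
// reconstruction also sums to 1 and the KL reduces to
//   const - sum_{A_ij > 0} A_ij log B_ij.
// We track ll = sum A_ij log B_ij, which is non-decreasing under these
// updates; convergence is declared when its increase drops below tol.
//
// [[Rcpp::export]]
List facet_fit_cpp(NumericMatrix A, NumericMatrix X0, NumericVector lambda0,
                   double tol, int max_iter) {
  const int n = A.nrow();
  const int k = X0.ncol();
  const double eps = 1e-12;

  NumericMatrix X = clone(X0);
  NumericVector lam = clone(lambda0);
  NumericMatrix B(n, n), R(n, n), RX(n, k), M(n, k);

  double ll_prev = R_NegInf;
  bool converged = false;
  bool monotone = true;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // B = X diag(lam) X^T
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        double b = 0.0;
        for (int c = 0; c < k; ++c) b += X(i, c) * lam[c] * X(j, c);
        B(i, j) = b;
        B(j, i) = b;
      }
    }
    // log-likelihood and ratio matrix
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        double a = A(i, j);
        if (a > 0.0) {
          double b = B(i, j) > eps ? B(i, j) : eps;
          ll += a * std::log(b);
          R(i, j) = a / b;
        } else {
          R(i, j) = 0.0;
        }
      }
    }
    if (ll < ll_prev - 1e-8) monotone = false;
    if (iter > 0 && std::fabs(ll - ll_prev) < tol) {
      converged = true;
      ll_prev = ll;
      break;
    }
    ll_prev = ll;

    // M = X * (R X) elementwise; column sums give the lambda update factor
    for (int c = 0; c < k; ++c) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) s += R(i, j) * X(j, c);
        RX(i, c) = s;
      }
    }
    double lamsum = 0.0;
    for (int c = 0; c < k; ++c) {
      double colsum = 0.0;
      for (int i = 0; i < n; ++i) {
        M(i, c) = X(i, c) * RX(i, c);
        colsum += M(i, c);
      }
      if (colsum > eps) {
        for (int i = 0; i < n; ++i) X(i, c) = M(i, c) / colsum;
      }
      lam[c] = lam[c] * (colsum > eps ? colsum : eps);
      lamsum += lam[c];
    }
    for (int c = 0; c < k; ++c) lam[c] /= lamsum;
  }

  return List::create(_["X"] = X, _["lambda"] = lam,
                      _["loglik"] = ll_prev, _["iterations"] = iter,
                      _["converged"] = converged, _["monotone"] = monotone);
}
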