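#include <Rcpp.h>
using namespace Rcpp;

// Pathwise cyclic coordinate descent on precomputed Gram quantities.
// Minimizes (1/2n)||y - Xb||^2 + lambda*||b||_1 given XtX = X'X/n and
// Xty = X'y/n, warm-starting down the (decreasing) lambda grid.
// Returns a k x nlambda coefficient matrix.
// [[Rcpp::export]]
NumericMatrix lasso_path_cpp(NumericMatrix XtX, NumericVector Xty,
                             NumericVector lambdas, NumericVector beta0,
                             double tol, int max_iter) {
  const int k = Xty.size();
  const int L = lambdas.size();
  NumericMatrix out(k, L);
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> d(k);
  for (int j = 0; j < k; ++j) d[j] = XtX(j, j);
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    for (int it = 0; it < max_iter; ++it) {
      double delta = 0.0;
      for (int j = 0; j < k; ++j) {
        if (d[j] <= 0.0) { beta[j] = 0.0; continue; }
        double rho = Xty[j] + d[j] * beta[j];
        for (int m = 0; m < k; ++m) rho -= XtX(j, m) * beta[m];
        double bj = 0.0;
        if (rho > lam) bj = (rho - lam) / d[j];
        else if (rho < -lam) bj = (rho + lam) / d[j];
        const double ch = std::abs(bj - beta[j]);
        if (ch > delta) delta = ch;
        beta[j] = bj;
      }
      if (delta < tol) break;
    }
    for (int j = 0; j < k; ++j) out(j, l) = beta[j];
  }
  return out;
}
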