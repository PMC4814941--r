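#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso objective
//   (1/2) ||y - Z beta||^2 + lambda * sum_j |beta_j|
// parameterised by the Gram matrix G = Z'Z and moment vector g = Z'y.
// Maintains q = G beta incrementally; convergence when the largest
// coefficient change in a full sweep falls below `tol`.
// [[Rcpp::export]]
List lasso_cd_gram(NumericMatrix G, NumericVector g, double lambda,
                   NumericVector beta0, double tol, int max_sweeps) {
  const int p = g.size();
  NumericVector beta = clone(beta0);
  std::vector<double> q(p, 0.0);
  for (int k = 0; k < p; ++k) {
    const double bk = beta[k];
    if (bk != 0.0)
      for (int j = 0; j < p; ++j) q[j] += G(j, k) * bk;
  }
  int sweep = 0;
  bool converged = false;
  for (; sweep < max_sweeps; ++sweep) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = G(j, j);
      if (gjj <= 0.0) continue;  // constant column: coefficient stays 0
      const double rho = g[j] - q[j] + gjj * beta[j];
      double bnew;
      if (rho > lambda)       bnew = (rho - lambda) / gjj;
      else if (rho < -lambda) bnew = (rho + lambda) / gjj;
      else                    bnew = 0.0;
      const double d = bnew - beta[j];
      if (d != 0.0) {
        for (int k = 0; k < p; ++k) q[k] += G(k, j) * d;
        beta[j] = bnew;
        const double ad = std::abs(d);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) { converged = true; ++sweep; break; }
  }
  return List::create(_["beta"] = beta, _["sweeps"] = sweep,
                      _["converged"] = converged);
}
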