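#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Weighted LASSO solved by cyclic coordinate descent with
// soft-thresholding along a decreasing lambda path (warm starts).
// Objective: (1 / (2 sum w)) * sum_i w_i (y_i - b0 - x_i.b)^2
//            + lambda * sum_j |b_j|
// The intercept is unpenalized.  Convergence: max absolute coefficient
// change (including the intercept) below tol, verified on a full sweep;
// between full sweeps the iteration restricts itself to the active set.
// [[Rcpp::export]]
List lasso_cd_path(NumericMatrix X, NumericVector y, NumericVector w,
                   NumericVector lambda, double tol = 1e-7,
                   int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  const double *xp = X.begin(), *wp = w.begin();
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += wp[i];

  std::vector<double> d(p);          // (1/W) sum_i w_i x_ij^2
  for (int j = 0; j < p; ++j) {
    const double *xj = xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wp[i] * xj[i] * xj[i];
    d[j] = s / W;
  }

  std::vector<double> beta(p, 0.0), r(y.begin(), y.end());
  double b0 = 0.0;

  NumericMatrix betas(p, nl);
  NumericVector b0s(nl);
  IntegerVector iters(nl);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    int it = 0;

    // one coordinate sweep; active_only restricts to nonzero coefficients
    auto sweep = [&](bool active_only) -> double {
      double delta = 0.0, s = 0.0;
      for (int i = 0; i < n; ++i) s += wp[i] * r[i];
      double db0 = s / W;
      if (db0 != 0.0) {
        b0 += db0;
        for (int i = 0; i < n; ++i) r[i] -= db0;
        delta = std::fabs(db0);
      }
      for (int j = 0; j < p; ++j) {
        if (d[j] <= 0.0) continue;
        if (active_only && beta[j] == 0.0) continue;
        const double *xj = xp + (size_t)j * n;
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += wp[i] * xj[i] * r[i];
        rho = rho / W + d[j] * beta[j];
        double bnew = soft(rho, lam) / d[j];
        double db = bnew - beta[j];
        if (db != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * db;
          beta[j] = bnew;
          double adb = std::fabs(db);
          if (adb > delta) delta = adb;
        }
      }
      return delta;
    };

    for (;;) {
      double delta;
      do {
        delta = sweep(true);
        if (++it > maxit)
          stop("coordinate descent did not converge at lambda = %g (last delta %g)",
               lam, delta);
      } while (delta >= tol);
      delta = sweep(false);          // full sweep checks for activations
      if (++it > maxit)
        stop("coordinate descent did not converge at lambda = %g (last delta %g)",
             lam, delta);
      if (delta < tol) break;
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    b0s[l] = b0;
    iters[l] = it;
  }
  return List::create(_["beta0"] = b0s, _["beta"] = betas,
                      _["iters"] = iters);
}
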