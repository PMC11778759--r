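#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding operator S(z, t) = sign(z) * max(|z| - t, 0).
inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net along a descending lambda
// path, with warm starts and an active-set strategy.  Objective (intercept
// b0 unpenalized):
//   (1/(2n)) * ||y - b0 - X b||_2^2
//     + lambda * ( (1-alpha)/2 * ||b||_2^2 + alpha * ||b||_1 )
// The intercept is concentrated out by centering, so the solver works with
// the Gram matrix G = Xc'Xc/n and c = Xc'yc/n; the coordinate update is
//   b_j <- S(g_j + G_jj b_j, lambda*alpha) / (G_jj + lambda*(1-alpha))
// with the gradient vector g = c - G b maintained incrementally.  A lambda
// converges when the largest coefficient change in a full sweep is < tol.
//
// Returns a (q+2) x nlambda matrix: row 0 = intercept, rows 1..q =
// coefficients, last row = sweeps used (for convergence reporting).
// [[Rcpp::export(name = ".enet_path_cpp")]]
NumericMatrix enet_path_cpp(NumericMatrix X, NumericVector y,
                            NumericVector lambdas, double alpha,
                            double tol, int max_iter) {
  const int n = X.nrow(), q = X.ncol(), nlam = lambdas.size();
  NumericMatrix out(q + 2, nlam);

  std::vector<double> xm(q), G(q * q), c(q), b(q, 0.0), g(q);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  for (int j = 0; j < q; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    xm[j] = m / n;
  }
  for (int j = 0; j < q; ++j) {
    for (int k = 0; k <= j; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i)
        s += (X(i, j) - xm[j]) * (X(i, k) - xm[k]);
      G[j * q + k] = G[k * q + j] = s / n;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (X(i, j) - xm[j]) * (y[i] - ym);
    c[j] = s / n;
  }
  for (int j = 0; j < q; ++j) g[j] = c[j];  // b = 0 initially

  std::vector<int> active;
  active.reserve(q);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambdas[l];
    const double thr = lam * alpha;
    const double ridge = lam * (1.0 - alpha);
    int sweeps = 0;
    bool done = false;
    while (!done) {
      // full sweep over all coordinates; rebuild the active set
      double maxdel = 0.0;
      active.clear();
      for (int j = 0; j < q; ++j) {
        const double gjj = G[j * q + j];
        if (gjj <= 0.0) continue;
        double z = g[j] + gjj * b[j];
        double bnew = soft(z, thr) / (gjj + ridge);
        double del = bnew - b[j];
        if (del != 0.0) {
          const double* Gj = &G[j * q];
          for (int k = 0; k < q; ++k) g[k] -= del * Gj[k];
          b[j] = bnew;
          double ad = std::fabs(del);
          if (ad > maxdel) maxdel = ad;
        }
        if (b[j] != 0.0) active.push_back(j);
      }
      ++sweeps;
      if (maxdel < tol || sweeps >= max_iter) break;
      // inner sweeps restricted to the active set
      while (sweeps < max_iter) {
        double mdel = 0.0;
        for (int jj = (int)active.size() - 1; jj >= 0; --jj) {
          int j = active[jj];
          const double gjj = G[j * q + j];
          double z = g[j] + gjj * b[j];
          double bnew = soft(z, thr) / (gjj + ridge);
          double del = bnew - b[j];
          if (del != 0.0) {
            const double* Gj = &G[j * q];
            for (int k = 0; k < q; ++k) g[k] -= del * Gj[k];
            b[j] = bnew;
            double ad = std::fabs(del);
            if (ad > mdel) mdel = ad;
          }
        }
        ++sweeps;
        if (mdel < tol) break;
      }
      if (sweeps >= max_iter) break;
      // loop back for a confirming full sweep
    }
    (void)done;
    double b0 = ym;
    for (int j = 0; j < q; ++j) b0 -= xm[j] * b[j];
    out(0, l) = b0;
    for (int j = 0; j < q; ++j) out(j + 1, l) = b[j];
    out(q + 1, l) = sweeps;
  }
  return out;
}

// Coordinate descent for the covariance-form lasso used inside the graphical
// lasso block updates:
//   min_beta  (1/2) beta' W11 beta - s12' beta + rho * ||beta||_1
// W11 is (p-1) x (p-1) PD, s12 length p-1.  Warm-started from beta_init.
// [[Rcpp::export(name = ".lasso_cov_cpp")]]
NumericVector lasso_cov_cpp(NumericMatrix W11, NumericVector s12, double rho,
                            NumericVector beta_init, double tol, int max_iter) {
  const int m = s12.size();
  NumericVector beta = clone(beta_init);
  for (int iter = 0; iter < max_iter; ++iter) {
    double maxdel = 0.0;
    for (int j = 0; j < m; ++j) {
      double g = s12[j];
      for (int k = 0; k < m; ++k)
        if (k != j) g -= W11(j, k) * beta[k];
      double bnew = soft(g, rho) / W11(j, j);
      double del = bnew - beta[j];
      if (del != 0.0) {
        beta[j] = bnew;
        maxdel = std::max(maxdel, std::fabs(del));
      }
    }
    if (maxdel < tol) break;
  }
  return beta;
}
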