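#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for 0.5 B'DB - d'B + lambda * sum_j w_j |B_j|.
// D must be positive semidefinite with strictly positive diagonal; the
// caller handles the lambda = 0 case by a direct solve. Warm starts via
// `init`. Shared by the penalized Lin-Ying solver and the IRLS logistic
// LASSO (its Newton working problem).
// [[Rcpp::export(name = ".cd_quad")]]
NumericVector cd_quad(const NumericMatrix& D, const NumericVector& d,
                      double lambda, const NumericVector& w,
                      const NumericVector& init, double tol, int maxit) {
  const int p = d.size();
  NumericVector B = clone(init);
  NumericVector DB(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += D(j, k) * B[k];
    DB[j] = s;
  }
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double g = lambda * w[j];
      const double r = d[j] - DB[j] + D(j, j) * B[j];
      double bnew;
      if (r > g) bnew = (r - g) / D(j, j);
      else if (r < -g) bnew = (r + g) / D(j, j);
      else bnew = 0.0;
      const double diff = bnew - B[j];
      if (diff != 0.0) {
        for (int k = 0; k < p; ++k) DB[k] += D(k, j) * diff;
        if (std::abs(diff) > delta) delta = std::abs(diff);
        B[j] = bnew;
      }
    }
    if (delta < tol) break;
  }
  return B;
}

// Full IRLS logistic LASSO at a fixed penalty: Newton outer loop with the
// coordinate-descent kernel on the working quadratic. Xs is the
// standardized design without intercept; pf is the (already rescaled)
// penalty-factor vector; Binit has length p + 1 (intercept first).
// Returns c(B, dev_ratio). Only the lambda > 0 hot path lives here; the
// unpenalized limit stays in R where it is solved by damped Newton.
// [[Rcpp::export(name = ".irls_lasso")]]
NumericVector irls_lasso(const NumericMatrix& Xs, const NumericVector& y,
                         const NumericVector& w, double lambda,
                         const NumericVector& pf, const NumericVector& Binit,
                         double tol, int maxit) {
  const int n = Xs.nrow(), p = Xs.ncol(), q = p + 1;
  NumericVector B = clone(Binit);
  NumericMatrix D(q, q);
  NumericVector d(q), DB(q), mu(n), W(n), z(n);
  NumericVector pf_full(q);
  for (int j = 0; j < p; ++j) pf_full[j + 1] = pf[j];

  for (int it = 0; it < maxit; ++it) {
    // working response and weights
    for (int i = 0; i < n; ++i) {
      double eta = B[0];
      for (int j = 0; j < p; ++j) eta += Xs(i, j) * B[j + 1];
      double m = 1.0 / (1.0 + std::exp(-eta));
      double v = m * (1.0 - m);
      if (v < 1e-5) v = 1e-5;
      mu[i] = m;
      W[i] = w[i] * v;
      z[i] = eta + (y[i] - m) / v;
    }
    // D = Z'WZ / n, d = Z'Wz / n with Z = [1, Xs]
    std::fill(D.begin(), D.end(), 0.0);
    std::fill(d.begin(), d.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double wi = W[i], wzi = W[i] * z[i];
      D(0, 0) += wi;
      d[0] += wzi;
      for (int j = 0; j < p; ++j) {
        const double xj = Xs(i, j);
        D(0, j + 1) += wi * xj;
        d[j + 1] += wzi * xj;
        for (int k = j; k < p; ++k)
          D(j + 1, k + 1) += wi * xj * Xs(i, k);
      }
    }
    for (int j = 0; j < q; ++j)
      for (int k = 0; k < j; ++k) D(j, k) = D(k, j);
    for (int j = 0; j < q; ++j) {
      for (int k = 0; k < q; ++k) D(j, k) /= n;
      d[j] /= n;
    }
    // warm-started coordinate descent on the working quadratic
    NumericVector Bold = clone(B);
    for (int j = 0; j < q; ++j) {
      double s = 0.0;
      for (int k = 0; k < q; ++k) s += D(j, k) * B[k];
      DB[j] = s;
    }
    for (int cd = 0; cd < 100; ++cd) {
      double delta = 0.0;
      for (int j = 0; j < q; ++j) {
        const double g = lambda * pf_full[j];
        const double r = d[j] - DB[j] + D(j, j) * B[j];
        double bnew;
        if (r > g) bnew = (r - g) / D(j, j);
        else if (r < -g) bnew = (r + g) / D(j, j);
        else bnew = 0.0;
        const double diff = bnew - B[j];
        if (diff != 0.0) {
          for (int k = 0; k < q; ++k) DB[k] += D(k, j) * diff;
          if (std::abs(diff) > delta) delta = std::abs(diff);
          B[j] = bnew;
        }
      }
      if (delta < tol) break;
    }
    double outer = 0.0;
    for (int j = 0; j < q; ++j)
      if (std::abs(B[j] - Bold[j]) > outer) outer = std::abs(B[j] - Bold[j]);
    if (outer < tol) break;
  }
  // deviance ratio against the weighted intercept-only model
  double sy = 0.0, sw = 0.0;
  for (int i = 0; i < n; ++i) { sy += w[i] * y[i]; sw += w[i]; }
  double pbar = sy / sw;
  if (pbar < 1e-4) pbar = 1e-4;
  if (pbar > 1 - 1e-4) pbar = 1 - 1e-4;
  double dev = 0.0, dev0 = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = B[0];
    for (int j = 0; j < p; ++j) eta += Xs(i, j) * B[j + 1];
    double m = 1.0 / (1.0 + std::exp(-eta));
    if (m < 1e-12) m = 1e-12;
    if (m > 1 - 1e-12) m = 1 - 1e-12;
    dev += -2.0 * w[i] * (y[i] * std::log(m) + (1 - y[i]) * std::log(1 - m));
    dev0 += -2.0 * w[i] * (y[i] * std::log(pbar) + (1 - y[i]) * std::log(1 - pbar));
  }
  NumericVector out(q + 1);
  for (int j = 0; j < q; ++j) out[j] = B[j];
  out[q] = 1.0 - dev / dev0;
  return out;
}
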