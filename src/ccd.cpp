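#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net over a decreasing lambda path.
//
// Objective (per lambda, alpha):
//   (1/2n) * sum_i (y_i - b0 - sum_j x_ij b_j)^2
//     + lambda * sum_j pf_j * [ alpha*|b_j| + (1-alpha)/2 * b_j^2 ]
//
// Predictors are standardized internally to mean 0 / variance 1 (1/n
// denominator); coefficients are returned on the original scale.  The fit
// operates on a row subset of X (cross-validation folds) by copying the
// standardized subset into a contiguous working matrix once.
//
// Per lambda (warm-started from the previous one) the solver sweeps an
// eligible set chosen by the sequential strong rule
//   |g_j(beta(lambda_{l-1}))| >= alpha * pf_j * (2*lambda_l - lambda_{l-1}),
// iterating the active (nonzero) subset to convergence between eligible
// sweeps, and finishes with a KKT pass over all predictors that promotes any
// violator into the eligible set.  Unpenalized coordinates (pf = 0) are
// always eligible.  Convergence: max_j (delta beta_j)^2 < tol on the
// standardized scale.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".ccd_path_cpp")]]
List ccd_path_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                  double alpha, NumericVector lambda, NumericVector pf,
                  double tol, int max_iter, bool covariance_updates) {
  const int n = rows.size();
  const int p = X.ncol();
  const int K = lambda.size();

  std::vector<int> rw(n);
  for (int i = 0; i < n; ++i) rw[i] = rows[i] - 1;  // 1-based in, 0-based here

  // standardized working copy of the row subset (column-major, contiguous)
  std::vector<double> Xs((size_t)n * p);
  std::vector<double> xm(p), xs(p);
  std::vector<bool> skip(p, false);
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { double v = col[rw[i]]; s += v; ss += v * v; }
    xm[j] = s / n;
    double v = ss / n - xm[j] * xm[j];
    double *out = &Xs[(size_t)j * n];
    if (v <= 1e-12) {
      skip[j] = true; xs[j] = 1.0;
      for (int i = 0; i < n; ++i) out[i] = 0.0;
    } else {
      xs[j] = std::sqrt(v);
      double inv = 1.0 / xs[j], m = xm[j];
      for (int i = 0; i < n; ++i) out[i] = (col[rw[i]] - m) * inv;
    }
  }

  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[rw[i]];
  ym /= n;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[rw[i]] - ym;

  std::vector<double> b(p, 0.0);           // standardized-scale coefficients
  std::vector<bool> in_active(p, false);
  std::vector<int> active;                  // insertion-ordered nonzero set

  // covariance-update caches
  std::vector<double> c_y;
  std::vector<int> cov_slot(p, -1);
  std::vector< std::vector<double> > cov_cols;
  if (covariance_updates) {
    c_y.resize(p);
    for (int j = 0; j < p; ++j) {
      const double *xj = &Xs[(size_t)j * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * r[i];
      c_y[j] = s / n;
    }
  }
  auto ensure_cov = [&](int j) {
    if (cov_slot[j] >= 0) return;
    cov_slot[j] = (int)cov_cols.size();
    cov_cols.push_back(std::vector<double>(p));
    std::vector<double> &cc = cov_cols.back();
    const double *xj = &Xs[(size_t)j * n];
    for (int k = 0; k < p; ++k) {
      const double *xk = &Xs[(size_t)k * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * xk[i];
      cc[k] = s / n;
    }
  };

  // gradient of the squared-error part at coordinate j, current solution
  auto grad_at = [&](int j) -> double {
    if (covariance_updates) {
      double g = c_y[j];
      for (size_t a = 0; a < active.size(); ++a) {
        int k = active[a];
        if (b[k] != 0.0) g -= cov_cols[cov_slot[k]][j] * b[k];
      }
      return g;
    }
    const double *xj = &Xs[(size_t)j * n];
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * r[i];
    return s / n;
  };

  // single coordinate update; returns squared change
  auto update_coord = [&](int j, double lam) -> double {
    double z = grad_at(j) + b[j];
    double bn = soft(z, lam * alpha * pf[j]) / (1.0 + lam * (1.0 - alpha) * pf[j]);
    double d = bn - b[j];
    if (d == 0.0) return 0.0;
    if (!covariance_updates) {
      const double *xj = &Xs[(size_t)j * n];
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
    }
    b[j] = bn;
    if (bn != 0.0 && !in_active[j]) {
      in_active[j] = true;
      active.push_back(j);
      if (covariance_updates) ensure_cov(j);
    }
    return d * d;
  };

  // gradients at the previous lambda's solution, for the strong rule
  std::vector<double> g_prev(p, 0.0);
  for (int j = 0; j < p; ++j) if (!skip[j]) g_prev[j] = grad_at(j);

  std::vector<bool> eligible(p, false);
  std::vector<int> elig;

  NumericMatrix coefs(p, K);
  NumericVector intercepts(K);
  IntegerVector n_iter(K);
  LogicalVector converged(K);

  for (int l = 0; l < K; ++l) {
    const double lam = lambda[l];
    const double lam_prev = (l == 0) ? lam : lambda[l - 1];
    const double bound = 2.0 * lam - lam_prev;

    elig.clear();
    std::fill(eligible.begin(), eligible.end(), false);
    for (int j = 0; j < p; ++j) {
      if (skip[j]) continue;
      if (pf[j] == 0.0 || b[j] != 0.0 ||
          std::fabs(g_prev[j]) >= alpha * pf[j] * bound) {
        eligible[j] = true;
        elig.push_back(j);
      }
    }

    int iter = 0;
    bool ok = false;
    while (iter < max_iter) {
      // sweep the eligible set
      double dlx = 0.0;
      for (size_t e = 0; e < elig.size(); ++e) {
        double d2 = update_coord(elig[e], lam);
        if (d2 > dlx) dlx = d2;
      }
      ++iter;
      if (dlx >= tol) {
        // iterate the active subset until stable
        while (iter < max_iter) {
          double dla = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            double d2 = update_coord(active[a], lam);
            if (d2 > dla) dla = d2;
          }
          ++iter;
          if (dla < tol) break;
        }
        continue;
      }
      // eligible set converged: KKT pass over the excluded coordinates
      bool violation = false;
      for (int j = 0; j < p; ++j) {
        if (skip[j] || eligible[j]) continue;
        double g = grad_at(j);
        g_prev[j] = g;
        if (std::fabs(g) > lam * alpha * pf[j]) {
          eligible[j] = true;
          elig.push_back(j);
          violation = true;
        }
      }
      ++iter;
      if (!violation) { ok = true; break; }
    }

    // refresh gradients on the eligible set for the next strong-rule screen
    for (size_t e = 0; e < elig.size(); ++e) g_prev[elig[e]] = grad_at(elig[e]);

    converged[l] = ok;
    n_iter[l] = iter;

    // original-scale coefficients and intercept
    double b0 = ym;
    for (int j = 0; j < p; ++j) {
      double cj = skip[j] ? 0.0 : b[j] / xs[j];
      coefs(j, l) = cj;
      b0 -= cj * xm[j];
    }
    intercepts[l] = b0;
  }

  return List::create(_["coefs"] = coefs, _["intercepts"] = intercepts,
                      _["n_iter"] = n_iter, _["converged"] = converged);
}

// Per-SNP sums of squares over a row subset.
// [[Rcpp::export(name = ".col_sumsq_cpp")]]
NumericVector col_sumsq_cpp(NumericMatrix X, IntegerVector rows) {
  const int n = rows.size();
  const int p = X.ncol();
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double *col = &X(0, j);
    for (int i = 0; i < n; ++i) { double v = col[rows[i] - 1]; s += v * v; }
    out[j] = s;
  }
  return out;
}

// Per-SNP inner products with a vector over a row subset, for lambda_max and
// the single-marker scan: returns <x_j, v> for each column j.
// [[Rcpp::export(name = ".col_crossprod_cpp")]]
NumericVector col_crossprod_cpp(NumericMatrix X, NumericVector v, IntegerVector rows) {
  const int n = rows.size();
  const int p = X.ncol();
  NumericVector out(p);
  std::vector<int> rw(n);
  for (int i = 0; i < n; ++i) rw[i] = rows[i] - 1;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double *col = &X(0, j);
    for (int i = 0; i < n; ++i) s += col[rw[i]] * v[i];
    out[j] = s;
  }
  return out;
}
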