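#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Cyclic coordinate descent for the lasso,
//   minimize (1/2n) * sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j |b_j|,
// solved on standardized predictors (mean 0, population SD 1) with an
// unpenalized intercept, warm-started along a decreasing lambda grid.
//
// The solver works on sufficient statistics (covariance updates): with
// Gs = X~'X~/n (standardized Gram, unit diagonal) and g = X~'yc/n, the
// coordinate update is beta_j <- S(g_j - sum_{k!=j} Gs_jk beta_k, lambda).
// The running vector s = Gs * beta is maintained incrementally, and each
// penalty value alternates full sweeps with sweeps over the active set
// (glmnet's strategy), which makes leave-one-out refits cheap.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One path solve given standardized sufficient statistics.
// Gs: p x p column-major; g: p; beta_out: L x p (solutions per lambda).
static void cd_solve_gram(const std::vector<double>& Gs,
                          const std::vector<double>& g, int p,
                          const std::vector<bool>& keep,
                          const NumericVector& lambda, double tol,
                          int max_sweeps, std::vector<double>& beta_out,
                          IntegerVector* sweeps_out) {
  const int L = lambda.size();
  std::vector<double> beta(p, 0.0), s(p, 0.0);
  std::vector<int> active;
  active.reserve(p);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int sweeps_used = 0;
    bool converged = false;
    while (!converged && sweeps_used < max_sweeps) {
      // full sweep over all coordinates
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (!keep[j]) continue;
        const double z = g[j] - s[j] + beta[j];
        const double bnew = soft_threshold(z, lam);
        const double d = bnew - beta[j];
        if (d != 0.0) {
          const double* gj = &Gs[(size_t)j * p];
          for (int k = 0; k < p; ++k) s[k] += gj[k] * d;
          beta[j] = bnew;
          const double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }
      ++sweeps_used;
      if (max_delta < tol) { converged = true; break; }
      // inner sweeps over the current active set until stable
      active.clear();
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) active.push_back(j);
      while (sweeps_used < max_sweeps) {
        double md = 0.0;
        for (int a : active) {
          const double z = g[a] - s[a] + beta[a];
          const double bnew = soft_threshold(z, lam);
          const double d = bnew - beta[a];
          if (d != 0.0) {
            const double* ga = &Gs[(size_t)a * p];
            for (int k = 0; k < p; ++k) s[k] += ga[k] * d;
            beta[a] = bnew;
            const double ad = std::fabs(d);
            if (ad > md) md = ad;
          }
        }
        ++sweeps_used;
        if (md < tol) break;
      }
    }
    if (sweeps_out) (*sweeps_out)[l] = sweeps_used;
    for (int j = 0; j < p; ++j) beta_out[(size_t)l * p + j] = beta[j];
  }
}

// Standardized sufficient statistics from raw cross-products of a subset of
// size n: G = X'X, xsum = colSums(X), xy = X'y, ysum = sum(y).
static void make_gram(const std::vector<double>& G,
                      const std::vector<double>& xsum,
                      const std::vector<double>& xy, double ysum, int n,
                      int p, std::vector<double>& Gs, std::vector<double>& g,
                      std::vector<double>& center, std::vector<double>& scale,
                      std::vector<bool>& keep) {
  Gs.assign((size_t)p * p, 0.0);
  g.assign(p, 0.0);
  center.assign(p, 0.0);
  scale.assign(p, 0.0);
  keep.assign(p, true);
  const double ybar = ysum / n;
  for (int j = 0; j < p; ++j) {
    center[j] = xsum[j] / n;
    const double v = G[(size_t)j * p + j] / n - center[j] * center[j];
    if (v <= 1e-14) { keep[j] = false; scale[j] = 0.0; }
    else scale[j] = std::sqrt(v);
  }
  for (int j = 0; j < p; ++j) {
    if (!keep[j]) continue;
    g[j] = (xy[j] / n - center[j] * ybar) / scale[j];
    for (int k = 0; k < p; ++k) {
      if (!keep[k]) continue;
      Gs[(size_t)j * p + k] =
          (G[(size_t)j * p + k] / n - center[j] * center[k]) /
          (scale[j] * scale[k]);
    }
  }
}

static void raw_crossprods(const NumericMatrix& X, const NumericVector& y,
                           std::vector<double>& G, std::vector<double>& xsum,
                           std::vector<double>& xy, double& ysum) {
  const int n = X.nrow(), p = X.ncol();
  G.assign((size_t)p * p, 0.0);
  xsum.assign(p, 0.0);
  xy.assign(p, 0.0);
  ysum = 0.0;
  for (int i = 0; i < n; ++i) ysum += y[i];
  for (int j = 0; j < p; ++j) {
    const NumericMatrix::ConstColumn xj = X.column(j);
    double s = 0.0, sy = 0.0;
    for (int i = 0; i < n; ++i) { s += xj[i]; sy += xj[i] * y[i]; }
    xsum[j] = s;
    xy[j] = sy;
    for (int k = j; k < p; ++k) {
      const NumericMatrix::ConstColumn xk = X.column(k);
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += xj[i] * xk[i];
      G[(size_t)j * p + k] = dot;
      G[(size_t)k * p + j] = dot;
    }
  }
}

// [[Rcpp::export]]
List cd_path_cpp(NumericMatrix X, NumericVector y, NumericVector lambda,
                 double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  std::vector<double> G, xsum, xy;
  double ysum;
  raw_crossprods(X, y, G, xsum, xy, ysum);
  std::vector<double> Gs, g, center, scale;
  std::vector<bool> keep;
  make_gram(G, xsum, xy, ysum, n, p, Gs, g, center, scale, keep);

  std::vector<double> beta_std((size_t)L * p, 0.0);
  IntegerVector sweeps(L);
  cd_solve_gram(Gs, g, p, keep, lambda, tol, max_sweeps, beta_std, &sweeps);

  const double ybar = ysum / n;
  NumericMatrix beta(p, L);
  NumericVector a0(L);
  for (int l = 0; l < L; ++l) {
    double dot = 0.0;
    for (int j = 0; j < p; ++j) {
      const double b = keep[j] ? beta_std[(size_t)l * p + j] / scale[j] : 0.0;
      beta(j, l) = b;
      dot += b * center[j];
    }
    a0[l] = ybar - dot;
  }
  return List::create(_["beta"] = beta, _["a0"] = a0, _["sweeps"] = sweeps,
                      _["center"] = NumericVector(center.begin(), center.end()),
                      _["scale"] = NumericVector(scale.begin(), scale.end()));
}

// Leave-one-out CV: the fold Gram is a rank-one downdate of the full raw
// cross-products, so each of the n refits costs O(p^2) setup plus the
// coordinate-descent sweeps; folds re-standardize internally. Predictors
// degenerate within a fold are dropped for that fold.
// [[Rcpp::export]]
List cd_loocv_cpp(NumericMatrix X, NumericVector y, NumericVector lambda,
                  double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  std::vector<double> G, xsum, xy;
  double ysum;
  raw_crossprods(X, y, G, xsum, xy, ysum);

  NumericMatrix errs(n, L);
  std::vector<double> Gf((size_t)p * p), xsumf(p), xyf(p);
  std::vector<double> Gs, g, center, scale, beta_std((size_t)L * p);
  std::vector<bool> keep;
  for (int hold = 0; hold < n; ++hold) {
    for (int j = 0; j < p; ++j) {
      const double xh = X(hold, j);
      xsumf[j] = xsum[j] - xh;
      xyf[j] = xy[j] - xh * y[hold];
      for (int k = 0; k < p; ++k)
        Gf[(size_t)j * p + k] = G[(size_t)j * p + k] - xh * X(hold, k);
    }
    const double ysumf = ysum - y[hold];
    make_gram(Gf, xsumf, xyf, ysumf, n - 1, p, Gs, g, center, scale, keep);
    std::fill(beta_std.begin(), beta_std.end(), 0.0);
    cd_solve_gram(Gs, g, p, keep, lambda, tol, max_sweeps, beta_std, nullptr);
    const double ybar = ysumf / (n - 1);
    for (int l = 0; l < L; ++l) {
      double pred = ybar;
      for (int j = 0; j < p; ++j) {
        if (!keep[j]) continue;
        const double b = beta_std[(size_t)l * p + j] / scale[j];
        pred += b * (X(hold, j) - center[j]);
      }
      const double e = y[hold] - pred;
      errs(hold, l) = e * e;
    }
  }
  NumericVector cv_mse(L), cv_se(L);
  for (int l = 0; l < L; ++l) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += errs(i, l);
    m /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = errs(i, l) - m;
      v += d * d;
    }
    v /= (n - 1);
    cv_mse[l] = m;
    cv_se[l] = std::sqrt(v / n);
  }
  return List::create(_["cv_mse"] = cv_mse, _["cv_se"] = cv_se,
                      _["errors"] = errs);
}
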