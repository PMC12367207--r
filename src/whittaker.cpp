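#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Band storage (lower): band[b * n + j] holds A[j + b, j], 0 <= b <= p.
// The system matrix W + lam * D'D has bandwidth p (1 or 2).

// Lower bands of lam * D'D, D = order-p forward difference operator
// ((n - p) x n). Row k of D has entries binom(p, i) * (-1)^(p - i) at
// column k + i.
static void penalty_bands(int n, double lam, int p, std::vector<double>& pen) {
  std::vector<double> c(p + 1);
  for (int i = 0; i <= p; ++i) {
    double bi = 1.0;
    for (int j = 0; j < i; ++j) bi = bi * (p - j) / (j + 1);
    c[i] = bi * (((p - i) % 2 == 0) ? 1.0 : -1.0);
  }
  pen.assign((size_t)(p + 1) * n, 0.0);
  for (int k = 0; k <= n - p - 1; ++k) {
    for (int i = 0; i <= p; ++i) {
      for (int l = i; l <= p; ++l) {
        pen[(size_t)(l - i) * n + (k + i)] += c[i] * c[l];
      }
    }
  }
  for (size_t t = 0; t < pen.size(); ++t) pen[t] *= lam;
}

// In-place banded Cholesky A = L L' then solve A z = rhs.
// Returns false if not numerically positive definite.
static bool band_chol_solve(std::vector<double>& band,
                            const std::vector<double>& rhs,
                            std::vector<double>& z, int n, int p) {
  double* b0 = band.data();
  for (int j = 0; j < n; ++j) {
    double d = b0[j];
    int k0 = j - p > 0 ? j - p : 0;
    for (int k = k0; k < j; ++k) {
      double ljk = b0[(size_t)(j - k) * n + k];
      d -= ljk * ljk;
    }
    if (!(d > 0.0) || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    b0[j] = d;
    int imax = j + p < n - 1 ? j + p : n - 1;
    for (int i = j + 1; i <= imax; ++i) {
      double s = b0[(size_t)(i - j) * n + j];
      int kk0 = i - p > 0 ? i - p : 0;
      for (int k = kk0; k < j; ++k) {
        s -= b0[(size_t)(i - k) * n + k] * b0[(size_t)(j - k) * n + k];
      }
      b0[(size_t)(i - j) * n + j] = s / d;
    }
  }
  z.assign(rhs.begin(), rhs.end());
  for (int i = 0; i < n; ++i) {           // forward: L u = rhs
    double s = z[i];
    int k0 = i - p > 0 ? i - p : 0;
    for (int k = k0; k < i; ++k) s -= b0[(size_t)(i - k) * n + k] * z[k];
    z[i] = s / b0[i];
  }
  for (int i = n - 1; i >= 0; --i) {      // backward: L' z = u
    double s = z[i];
    int kmax = i + p < n - 1 ? i + p : n - 1;
    for (int k = i + 1; k <= kmax; ++k) s -= b0[(size_t)(k - i) * n + i] * z[k];
    z[i] = s / b0[i];
  }
  return true;
}

// Full airPLS loop: iteratively reweighted Whittaker smoothing.
// Weights: 0 where residual d_i = y_i - z_i >= 0; exp(t |d_i| / m) where
// d_i < 0 (m = negative-residual mass); endpoints anchored at
// exp(t max|d_-| / m). Exponent clipped at 700, m floored at
// eps * sum|y|. Stops when m < tau * sum|y| or t == max_iter. On exit, w
// holds the weights actually used for the returned z.
static int airpls_core(const double* y, int n, double lam, double tau, int p,
                       int max_iter, std::vector<double>& z,
                       std::vector<double>& w, bool& converged) {
  std::vector<double> pen, band, rhs(n);
  penalty_bands(n, lam, p, pen);
  w.assign(n, 1.0);
  double absy = 0.0;
  for (int i = 0; i < n; ++i) absy += std::fabs(y[i]);
  const double m_floor = std::numeric_limits<double>::epsilon() * absy;
  converged = false;
  int t;
  for (t = 1; t <= max_iter; ++t) {
    band = pen;
    for (int i = 0; i < n; ++i) {
      band[i] += w[i];
      rhs[i] = w[i] * y[i];
    }
    if (!band_chol_solve(band, rhs, z, n, p)) {
      // weights collapsed below the penalty null-space dimension: keep the
      // previous iterate and stop
      t -= 1;
      converged = true;
      break;
    }
    double m = 0.0, dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      if (d < 0.0) {
        m += -d;
        if (-d > dmax) dmax = -d;
      }
    }
    if (m < tau * absy) {
      converged = true;
      break;
    }
    if (t == max_iter) break;  // keep w as the weights used for z
    if (m < m_floor) m = m_floor;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      if (d >= 0.0) {
        w[i] = 0.0;
      } else {
        double a = t * (-d) / m;
        if (a > 700.0) a = 700.0;
        w[i] = std::exp(a);
      }
    }
    double aend = t * dmax / m;
    if (aend > 700.0) aend = 700.0;
    w[0] = std::exp(aend);
    w[n - 1] = w[0];
  }
  if (t > max_iter) t = max_iter;
  if (z.empty()) z.assign(y, y + n);
  return t;
}

// [[Rcpp::export(name = ".whittaker_solve_cpp")]]
NumericVector whittaker_solve_cpp(NumericVector y, NumericVector w,
                                  double lam, int p) {
  const int n = y.size();
  std::vector<double> pen, rhs(n), z;
  penalty_bands(n, lam, p, pen);
  for (int i = 0; i < n; ++i) {
    pen[i] += w[i];
    rhs[i] = w[i] * y[i];
  }
  if (!band_chol_solve(pen, rhs, z, n, p))
    stop("penalized system is singular (weights do not pin down the penalty null space)");
  return NumericVector(z.begin(), z.end());
}

// [[Rcpp::export(name = ".airpls_cpp")]]
List airpls_cpp(NumericVector y, double lam, double tau, int p, int max_iter) {
  std::vector<double> z, w;
  bool converged;
  int iters = airpls_core(y.begin(), y.size(), lam, tau, p, max_iter, z, w,
                          converged);
  return List::create(_["baseline"] = NumericVector(z.begin(), z.end()),
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = iters,
                      _["converged"] = converged);
}

// Batch grid evaluation: MAE between the airPLS baseline and the known
// true baseline for every (lambda, tau) pair. Same kernel as .airpls_cpp,
// so grid MAEs agree exactly with a fresh fit at the same pair.
// [[Rcpp::export(name = ".evaluate_grid_cpp")]]
NumericVector evaluate_grid_cpp(NumericVector y, NumericVector truth,
                                NumericVector lams, NumericVector taus,
                                int p, int max_iter) {
  const int n = y.size(), m = lams.size();
  NumericVector out(m);
  std::vector<double> z, w;
  bool converged;
  for (int j = 0; j < m; ++j) {
    airpls_core(y.begin(), n, lams[j], taus[j], p, max_iter, z, w, converged);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::fabs(z[i] - truth[i]);
    out[j] = s / n;
  }
  return out;
}
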