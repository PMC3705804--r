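#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// eps-SVR dual in the beta parametrization (beta_i = alpha_i - alpha_i^*):
//   maximize W(beta) = -1/2 beta' K beta + y' beta - eps * sum_i |beta_i|
//   subject to sum_i beta_i = 0, -C <= beta_i <= C.
//
// SMO-style pairwise ascent with most-violating-pair working-set selection:
// each iteration moves mass delta from coordinate j to coordinate i chosen
// by the extreme directional derivatives, and the one-dimensional piecewise
// quadratic in delta is maximized exactly (stationary point of every sign
// region plus all breakpoints). Deterministic given input order: ties in the
// selection resolve to the lowest index.

static double delta_obj(double eta, double g, double eps, double bi,
                        double bj, double d) {
  return -0.5 * eta * d * d + g * d -
         eps * (std::fabs(bi + d) - std::fabs(bi)) -
         eps * (std::fabs(bj - d) - std::fabs(bj));
}

// exact maximizer of delta_obj over delta in [L, U]; returns gain via *gain
static double best_delta(double eta, double g, double eps, double bi,
                         double bj, double L, double U, double *gain) {
  double cand[9];
  int nc = 0;
  cand[nc++] = L;
  cand[nc++] = U;
  if (-bi > L && -bi < U) cand[nc++] = -bi;
  if (bj > L && bj < U) cand[nc++] = bj;
  if (eta > 1e-12) {
    for (int s1 = -1; s1 <= 1; s1 += 2) {
      for (int s2 = -1; s2 <= 1; s2 += 2) {
        double d = (g - eps * s1 + eps * s2) / eta;
        if (d < L) d = L;
        if (d > U) d = U;
        cand[nc++] = d;
      }
    }
  }
  double bd = 0.0, bg = 0.0;
  for (int c = 0; c < nc; ++c) {
    double gn = delta_obj(eta, g, eps, bi, bj, cand[c]);
    if (gn > bg) { bg = gn; bd = cand[c]; }
  }
  *gain = bg;
  return bd;
}

// core solver on a kernel matrix stored as a flat n*n array (column-major)
static void smo_solve(const double *K, const double *y, int n, double C,
                      double eps, double tol, int max_iter, double *beta,
                      double *f, double *objective, int *iters) {
  for (int i = 0; i < n; ++i) { beta[i] = 0.0; f[i] = 0.0; }
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // directional derivatives: up_i = right derivative (increase beta_i),
    // dn_i = left derivative (decrease beta_i)
    int bi_idx = -1, bj_idx = -1;
    double up_best = -HUGE_VAL, dn_best = HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - f[i];
      if (beta[i] < C) {
        double up = r - eps * (beta[i] >= 0.0 ? 1.0 : -1.0);
        if (up > up_best) { up_best = up; bi_idx = i; }
      }
      if (beta[i] > -C) {
        double dn = r - eps * (beta[i] > 0.0 ? 1.0 : -1.0);
        if (dn < dn_best) { dn_best = dn; bj_idx = i; }
      }
    }
    if (bi_idx < 0 || bj_idx < 0 || bi_idx == bj_idx) break;
    if (up_best - dn_best < tol) break;
    int i = bi_idx, j = bj_idx;
    double eta = K[i + n * i] + K[j + n * j] - 2.0 * K[i + n * j];
    double g = (y[i] - f[i]) - (y[j] - f[j]);
    double L = std::max(-C - beta[i], beta[j] - C);
    double U = std::min(C - beta[i], beta[j] + C);
    if (U <= L) break;
    double gain = 0.0;
    double d = best_delta(eta, g, eps, beta[i], beta[j], L, U, &gain);
    if (gain <= 1e-15) break;
    beta[i] += d;
    beta[j] -= d;
    const double *Ki = K + (size_t)n * i;
    const double *Kj = K + (size_t)n * j;
    for (int r = 0; r < n; ++r) f[r] += d * (Ki[r] - Kj[r]);
  }
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    obj += y[i] * beta[i] - eps * std::fabs(beta[i]) - 0.5 * beta[i] * f[i];
  }
  *objective = obj;
  *iters = it;
}

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double grad_tol, int max_iter) {
  int n = K.nrow();
  NumericVector beta(n), f(n);
  double obj = 0.0;
  int iters = 0;
  smo_solve(REAL(K), REAL(y), n, C, eps, grad_tol, max_iter,
            REAL(beta), REAL(f), &obj, &iters);
  return List::create(_["beta"] = beta, _["f"] = f, _["objective"] = obj,
                      _["iterations"] = iters);
}

// KKT-based bias recovery shared with the R side: free support vectors pin
// the bias; otherwise the midpoint of the admissible interval is used
static double recover_bias(const double *beta, const double *y,
                           const double *f, int n, double C, double eps,
                           double kkt_tol) {
  double s = 0.0;
  int nfree = 0;
  for (int i = 0; i < n; ++i) {
    if (beta[i] > kkt_tol && beta[i] < C - kkt_tol) {
      s += y[i] - eps - f[i];
      ++nfree;
    } else if (beta[i] < -kkt_tol && beta[i] > -C + kkt_tol) {
      s += y[i] + eps - f[i];
      ++nfree;
    }
  }
  if (nfree > 0) return s / nfree;
  double lo = -HUGE_VAL, hi = HUGE_VAL;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - f[i];
    if (beta[i] >= C - kkt_tol) {
      hi = std::min(hi, r - eps);
    } else if (beta[i] <= -C + kkt_tol) {
      lo = std::max(lo, r + eps);
    } else {
      lo = std::max(lo, r - eps);
      hi = std::min(hi, r + eps);
    }
  }
  if (std::isfinite(lo) && std::isfinite(hi)) return 0.5 * (lo + hi);
  return 0.0;
}

// Full leave-one-out cross-validation loop for min-max-scaled RBF eps-SVR,
// kept in compiled code because wrapper feature selection evaluates
// thousands of candidate subsets. Per fold: refit the min-max scaler on the
// n-1 training rows, build the kernel, solve the dual, recover the bias and
// predict the held-out row. Mirrors train_svr()/predict() exactly.
// [[Rcpp::export]]
NumericVector svr_loocv_cpp(NumericMatrix X, NumericVector y, double C,
                            double eps, double gamma, double grad_tol,
                            int max_iter, double kkt_tol) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> Xs((size_t)(n - 1) * p), ytr(n - 1), xq(p);
  std::vector<double> K((size_t)(n - 1) * (n - 1));
  std::vector<double> beta(n - 1), f(n - 1);
  std::vector<double> fmin(p), frange(p);

  for (int hold = 0; hold < n; ++hold) {
    int m = 0;
    // training target min/max
    double ymin = HUGE_VAL, ymax = -HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      double yi = y[i];
      if (yi < ymin) ymin = yi;
      if (yi > ymax) ymax = yi;
      ++m;
    }
    double yrange = ymax - ymin;
    if (yrange <= 0.0) stop("constant activity in LOOCV fold %d", hold + 1);
    for (int c = 0; c < p; ++c) {
      double lo = HUGE_VAL, hi = -HUGE_VAL;
      for (int i = 0; i < n; ++i) {
        if (i == hold) continue;
        double v = X(i, c);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      fmin[c] = lo;
      frange[c] = (hi > lo) ? hi - lo : 1.0;
    }
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int c = 0; c < p; ++c) {
        Xs[(size_t)r + (size_t)m * c] = (X(i, c) - fmin[c]) / frange[c];
      }
      ytr[r] = (y[i] - ymin) / yrange;
      ++r;
    }
    for (int c = 0; c < p; ++c) xq[c] = (X(hold, c) - fmin[c]) / frange[c];
    for (int a = 0; a < m; ++a) {
      K[(size_t)a + (size_t)m * a] = 1.0;
      for (int b = a + 1; b < m; ++b) {
        double d2 = 0.0;
        for (int c = 0; c < p; ++c) {
          double d = Xs[(size_t)a + (size_t)m * c] - Xs[(size_t)b + (size_t)m * c];
          d2 += d * d;
        }
        double kv = std::exp(-gamma * d2);
        K[(size_t)a + (size_t)m * b] = kv;
        K[(size_t)b + (size_t)m * a] = kv;
      }
    }
    double obj = 0.0;
    int iters = 0;
    smo_solve(K.data(), ytr.data(), m, C, eps, grad_tol, max_iter,
              beta.data(), f.data(), &obj, &iters);
    double bias = recover_bias(beta.data(), ytr.data(), f.data(), m, C, eps,
                               kkt_tol);
    double pred = bias;
    for (int a = 0; a < m; ++a) {
      if (beta[a] == 0.0) continue;
      double d2 = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = Xs[(size_t)a + (size_t)m * c] - xq[c];
        d2 += d * d;
      }
      pred += beta[a] * std::exp(-gamma * d2);
    }
    out[hold] = yrange * pred + ymin;
  }
  return out;
}
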