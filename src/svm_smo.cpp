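// Pairwise coordinate solver for the soft-margin SVM dual with kernel
// K + lam*I: minimize 1/2 a'Qa - 1'a, Q_hk = y_h y_k Kt_hk, subject to
// 0 <= a_k <= C and sum a_k y_k = 0. Working-set selection is the
// second-order rule: the maximally violating index i, then the partner j
// with the largest guaranteed objective decrease. The returned `gap`
// bounds the KKT violation of the reported point.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix Kt, NumericVector y, double C, double tol,
                   int max_iter) {
  int n = y.size();
  std::vector<double> alpha(n, 0.0), g(n, -1.0), v(n);
  long long it = 0;
  double gap = 0.0;
  const double eps = 1e-12;

  for (;;) {
    int i = -1, jmin = -1;
    double vmax = -HUGE_VAL, vmin = HUGE_VAL;
    for (int k = 0; k < n; ++k) {
      v[k] = -y[k] * g[k];
      bool up = (y[k] > 0 && alpha[k] < C - eps) ||
                (y[k] < 0 && alpha[k] > eps);
      bool lo = (y[k] < 0 && alpha[k] < C - eps) ||
                (y[k] > 0 && alpha[k] > eps);
      if (up && v[k] > vmax) { vmax = v[k]; i = k; }
      if (lo && v[k] < vmin) { vmin = v[k]; jmin = k; }
    }
    if (i < 0 || jmin < 0) { gap = 0.0; break; }
    gap = vmax - vmin;
    if (gap <= tol) break;
    if (it >= max_iter)
      stop("SVM solver did not converge in %d iterations (gap %g)",
           (int)it, gap);

    // second-order partner selection among the violating lower set
    int j = -1;
    double best = HUGE_VAL, a_best = 0.0;
    for (int k = 0; k < n; ++k) {
      bool lo = (y[k] < 0 && alpha[k] < C - eps) ||
                (y[k] > 0 && alpha[k] > eps);
      if (!lo) continue;
      double b = vmax - v[k];
      if (b <= 0) continue;
      double a2 = Kt(i, i) + Kt(k, k) - 2.0 * Kt(i, k);
      if (a2 < eps) a2 = eps;
      double score = -(b * b) / a2;
      if (score < best) { best = score; j = k; a_best = a2; }
    }
    if (j < 0) break;  // no admissible partner: optimal within tolerance

    double t_star = (vmax - v[j]) / a_best;
    double ub_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double ub_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    double t = t_star;
    if (ub_i < t) t = ub_i;
    if (ub_j < t) t = ub_j;
    alpha[i] += y[i] * t;
    alpha[j] -= y[j] * t;
    double ci = y[i] * t, cj = y[j] * t;
    for (int k = 0; k < n; ++k)
      g[k] += ci * y[k] * y[i] * Kt(k, i) - cj * y[k] * y[j] * Kt(k, j);
    ++it;
    if (it % 100000 == 0) {  // periodic refresh against gradient drift
      for (int k = 0; k < n; ++k) {
        double s = -1.0;
        for (int h = 0; h < n; ++h)
          s += alpha[h] * y[h] * y[k] * Kt(h, k);
        g[k] = s;
      }
    }
  }

  // bias from marginal support vectors, else the KKT band midpoint
  double bsum = 0.0; int bcnt = 0;
  for (int k = 0; k < n; ++k) {
    v[k] = -y[k] * g[k];
    if (alpha[k] > 1e-8 && alpha[k] < C - 1e-8) { bsum += v[k]; ++bcnt; }
  }
  double b;
  if (bcnt > 0) b = bsum / bcnt;
  else {
    double vmax = -HUGE_VAL, vmin = HUGE_VAL;
    for (int k = 0; k < n; ++k) {
      bool up = (y[k] > 0 && alpha[k] < C - eps) ||
                (y[k] < 0 && alpha[k] > eps);
      bool lo = (y[k] < 0 && alpha[k] < C - eps) ||
                (y[k] > 0 && alpha[k] > eps);
      if (up && v[k] > vmax) vmax = v[k];
      if (lo && v[k] < vmin) vmin = v[k];
    }
    b = (vmax + vmin) / 2.0;
  }
  return List::create(Named("alpha") = wrap(alpha), Named("b") = b,
                      Named("iterations") = (double)it,
                      Named("gap") = gap);
}
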