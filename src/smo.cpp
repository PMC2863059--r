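// Sequential minimal optimization for the generic dual
//   min_a  1/2 a' Q a + p' a   s.t.  y' a = 0,  0 <= a_i <= C_i
// with maximal-violating-pair working-set selection. Both C-SVC and eps-SVR
// reduce to this form (for SVR the 2n-variable doubled problem is passed in).
// Q is the label-signed kernel matrix: Q_ij = y_i y_j K_ij.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix Q, NumericVector p, NumericVector y,
               NumericVector C, double tol = 1e-3,
               int max_iter = 10000000) {
  const int n = Q.nrow();
  std::vector<double> alpha(n, 0.0), G(p.begin(), p.end());
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // i: argmax over I_up of -y_t G_t ; j: argmin over I_low of -y_t G_t
    double Gmax = -DBL_MAX, Gmin = DBL_MAX;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0)    : (alpha[t] < C[t]);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i == -1 || j == -1 || Gmax - Gmin < tol) { converged = true; break; }

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] * y[j] < 0) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t) G[t] += Q(t, i) * dai + Q(t, j) * daj;
    ++iter;
  }

  // rho such that the decision function is sum_i y_i a_i K(x_i, x) - rho
  double ub = DBL_MAX, lb = -DBL_MAX, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  const double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter,
                      _["converged"] = converged);
}
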