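// C-SVC dual solver (SMO with maximal-violating-pair working-set selection,
// as in LIBSVM's first-order rule) over a precomputed kernel matrix.
//
// The one-vs-rest SVM layer evaluates hundreds of thousands of small binary
// problems during incremental feature selection; solving the dual directly on
// a shared, incrementally updated kernel keeps that loop fast.  n here is a
// training-fold size (tens of samples), so dense O(n^2) bookkeeping is fine.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".smo_train_cpp")]]
List smo_train_cpp(NumericMatrix K, IntegerVector y, double C, double eps,
                   int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  // G_i = d/dalpha_i of 1/2 a'Qa - e'a, with Q_ij = y_i y_j K_ij
  std::vector<double> G(n, -1.0);

  int iter = 0;
  while (iter++ < max_iter) {
    // i: max -y_t G_t over I_up; j: min -y_t G_t over I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    // ||phi(x_i) - phi(x_j)||^2, the curvature along the feasible direction
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;

    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = ai_old - aj_old;
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = ai_old + aj_old;
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double di = alpha[i] - ai_old, dj = alpha[j] - aj_old;
    if (di == 0.0 && dj == 0.0) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(i, t) * di + y[j] * K(j, t) * dj);
  }

  // intercept: average over free SVs, else midpoint of the KKT bounds
  double rho_sum = 0.0; int n_free = 0;
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double v = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { rho_sum += v; n_free++; }
    else if ((y[t] == 1 && alpha[t] == 0) || (y[t] == -1 && alpha[t] == C)) {
      if (v < ub) ub = v;
    } else {
      if (v > lb) lb = v;
    }
  }
  double rho = n_free > 0 ? rho_sum / n_free : 0.5 * (ub + lb);
  // decision f(x) = sum_i alpha_i y_i K(x_i, x) - rho
  NumericVector coef(n);
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coef, _["rho"] = rho,
                      _["iter"] = iter);
}
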