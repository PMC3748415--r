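#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Sequential minimal optimization for the weighted SVM dual
//
//   min_a  1/2 a' Q a - 1' a   s.t.  0 <= a_i <= C,  sum_i a_i y_i = 0
//
// Q is the label-signed Gram matrix Q_ij = y_i y_j x_i' V^{-1} x_j, dense,
// positive semidefinite.  Working sets are maximum-violating pairs: the
// largest -y_i g_i over the "up" set against the smallest over the "down"
// set, where g = Q a - 1 is the dual gradient.  Each pair is solved in
// closed form along the equality-feasible line and clipped to the box.
//
// status: 0 converged, 1 pass budget exhausted, 2 unbounded (hard margin on
// non-separable data: alpha diverges).

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix Q, NumericVector y, double box_c,
                   double tol, int max_passes, NumericVector alpha0) {
  const int m = Q.nrow();
  const double TAU = 1e-12;
  const double ALPHA_DIVERGED = 1e8;
  std::vector<double> alpha(m, 0.0);
  std::vector<double> grad(m, -1.0); // gradient at alpha = 0
  if (alpha0.size() == m) {          // warm start from a feasible point
    for (int t = 0; t < m; ++t) alpha[t] = alpha0[t];
    for (int s = 0; s < m; ++s) {
      if (alpha[s] == 0.0) continue;
      const double as = alpha[s];
      const double *qs = &Q(0, s);
      for (int t = 0; t < m; ++t) grad[t] += qs[t] * as;
    }
  }
  int pass = 0;
  int status = 1;
  double viol = std::numeric_limits<double>::infinity();

  while (pass < max_passes) {
    // maximum violating pair
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0) ? (alpha[t] < box_c) : (alpha[t] > 0);
      const bool down = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < box_c);
      if (up && v > gmax) { gmax = v; i = t; }
      if (down && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0) { viol = 0.0; status = 0; break; }
    viol = gmax - gmin;
    if (viol <= tol) { status = 0; break; }

    // closed-form step for the pair, clipped to the box while preserving
    // y_i a_i + y_j a_j exactly
    double a2 = Q(i, i) + Q(j, j) - 2.0 * y[i] * y[j] * Q(i, j);
    if (a2 <= 0.0) a2 = TAU; // duplicate points: linear along the segment,
                             // the clip below lands on the better endpoint
    const double step = viol / a2;
    const double old_ai = alpha[i], old_aj = alpha[j];
    const double lin = y[i] * old_ai + y[j] * old_aj;
    alpha[i] = old_ai + y[i] * step;
    if (alpha[i] > box_c) alpha[i] = box_c;
    if (alpha[i] < 0.0) alpha[i] = 0.0;
    alpha[j] = y[j] * (lin - y[i] * alpha[i]);
    if (alpha[j] > box_c) alpha[j] = box_c;
    if (alpha[j] < 0.0) alpha[j] = 0.0;
    alpha[i] = y[i] * (lin - y[j] * alpha[j]);

    const double dai = alpha[i] - old_ai;
    const double daj = alpha[j] - old_aj;
    {
      const double *qi = &Q(0, i);
      const double *qj = &Q(0, j);
      for (int t = 0; t < m; ++t) grad[t] += qi[t] * dai + qj[t] * daj;
    }
    ++pass;

    if (!std::isfinite(box_c) &&
        (alpha[i] > ALPHA_DIVERGED || alpha[j] > ALPHA_DIVERGED)) {
      status = 2;
      break;
    }

    // periodic full refresh caps incremental floating-point drift
    if (pass % 1000 == 0) {
      for (int t = 0; t < m; ++t) grad[t] = -1.0;
      for (int s = 0; s < m; ++s) {
        if (alpha[s] == 0.0) continue;
        const double as = alpha[s];
        const double *qs = &Q(0, s);
        for (int t = 0; t < m; ++t) grad[t] += qs[t] * as;
      }
    }
  }

  // fresh gradient for the reported objective and violation
  for (int t = 0; t < m; ++t) grad[t] = -1.0;
  for (int s = 0; s < m; ++s) {
    if (alpha[s] == 0.0) continue;
    const double as = alpha[s];
    const double *qs = &Q(0, s);
    for (int t = 0; t < m; ++t) grad[t] += qs[t] * as;
  }
  double obj = 0.0;
  for (int t = 0; t < m; ++t) obj += alpha[t] * (grad[t] - 1.0);
  obj *= 0.5;

  if (status != 2) {
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0) ? (alpha[t] < box_c) : (alpha[t] > 0);
      const bool down = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < box_c);
      if (up && v > gmax) gmax = v;
      if (down && v < gmin) gmin = v;
    }
    viol = (std::isfinite(gmax) && std::isfinite(gmin)) ? gmax - gmin : 0.0;
    if (viol < 0.0) viol = 0.0;
    if (status == 1 && viol <= tol) status = 0;
  }

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["dual_objective"] = obj,
    _["n_passes"] = pass,
    _["converged"] = (status == 0),
    _["max_kkt_violation"] = viol,
    _["status"] = status);
}
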