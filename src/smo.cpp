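#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solved by sequential minimal optimization with
// maximal-violating-pair working-set selection:
//   min_a  0.5 * a' Q a - e' a,   Q_ij = y_i y_j K_ij
//   s.t.   y' a = 0,  0 <= a_i <= C
// Deterministic: no random initialization, ties broken by lowest index.
// eps is the stopping tolerance on the maximal KKT violation m(a) - M(a).

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double eps = 1e-10, double max_iter = 1e7) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  double iter = 0;
  for (; iter < max_iter; iter += 1) {
    // i: most violating in I_up, j: most violating in I_low
    int i = -1, j = -1;
    double m = -std::numeric_limits<double>::infinity();
    double M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m)  { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M <= eps) break;

    // two-variable subproblem along da_i = y_i * t, da_j = -y_j * t;
    // curvature of the dual along that direction is K_ii + K_jj - 2 K_ij
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad < 1e-12) quad = 1e-12;
    double t_step = (m - M) / quad;  // m - M = -(y_i G_i - y_j G_j)

    // box constraints for both coordinates
    double lo = -std::numeric_limits<double>::infinity();
    double hi =  std::numeric_limits<double>::infinity();
    if (y[i] > 0) { lo = std::max(lo, -alpha[i]);    hi = std::min(hi, C - alpha[i]); }
    else          { lo = std::max(lo, alpha[i] - C); hi = std::min(hi, alpha[i]); }
    if (y[j] > 0) { lo = std::max(lo, alpha[j] - C); hi = std::min(hi, alpha[j]); }
    else          { lo = std::max(lo, -alpha[j]);    hi = std::min(hi, C - alpha[j]); }
    if (t_step > hi) t_step = hi;
    if (t_step < lo) t_step = lo;
    if (t_step == 0.0) break;  // numerically stuck at the box

    const double dai = y[i] * t_step, daj = -y[j] * t_step;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }
  if (iter >= max_iter)
    stop("SMO did not converge within %.0f iterations", max_iter);

  // bias: average of y_i - f_i over free support vectors (f_i = sum a_j y_j K_ij);
  // note -y_i G_i = y_i - f_i. Fall back to the violation midpoint.
  double b_sum = 0.0; int b_cnt = 0;
  double m = -std::numeric_limits<double>::infinity();
  double M = std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { b_sum += v; ++b_cnt; }
    const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up && v > m)  m = v;
    if (low && v < M) M = v;
  }
  const double b = b_cnt > 0 ? b_sum / b_cnt : (m + M) / 2.0;

  // dual objective 0.5 a'Qa - e'a = 0.5 * sum a_i (G_i - 1)  since G = Qa - e
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj *= 0.5;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = b, _["objective"] = obj,
                      _["iterations"] = iter);
}
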