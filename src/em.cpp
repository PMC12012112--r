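#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama stepping for the OU (model = 0) and fold (model = 1) drifts,
// optionally tamed: drift term -U'/(1 + eps|U'|). k may vary per step
// (piecewise constant within a step, evaluated at the step's start). The
// basin-escape rule (fold only) is checked on the post-update state:
// X_j < -sqrt(k_j) - k_j/10. Plain-scheme divergence is flagged, not thrown.
//
// Returns: x (states after each step, length = steps actually taken),
// truncated_at (1-based step where the escape rule fired, or NA),
// diverged_at (1-based step where the state became non-finite, or NA).
// [[Rcpp::export]]
List em_path_cpp(int model, NumericVector k_schedule, NumericVector increments,
                 double dt, double eps, double x0, bool tamed,
                 bool stop_on_escape) {
  const int n = increments.size();
  std::vector<double> x;
  x.reserve(n);
  double xc = x0;
  int truncated_at = NA_INTEGER;
  int diverged_at = NA_INTEGER;

  for (int j = 0; j < n; ++j) {
    const double k = k_schedule.size() == 1 ? k_schedule[0] : k_schedule[j];
    // U'(x): k*x for OU, x^2 - k for fold (drift is -U')
    const double up = (model == 0) ? k * xc : xc * xc - k;
    const double d = tamed ? up / (1.0 + eps * std::fabs(up)) : up;
    xc = xc - d * dt + increments[j];
    if (!std::isfinite(xc)) {
      diverged_at = j + 1;
      break;
    }
    x.push_back(xc);
    if (stop_on_escape && model == 1 && xc < -std::sqrt(k) - k / 10.0) {
      truncated_at = j + 1;
      break;
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["truncated_at"] = truncated_at,
                      _["diverged_at"] = diverged_at);
}
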