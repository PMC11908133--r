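#include <Rcpp.h>
using namespace Rcpp;

// Linear birth-death realization started from one cell at `atma`, sampled
// at `times` (sorted, all >= atma). Per-cell birth rate `birth`, death rate
// `death` (net rate s = birth - death). Optionally rejection-conditioned on
// non-extinction by the first sample time (clones observed in data
// necessarily survived to observation). Above `det_threshold` cells the
// demographic fluctuations are negligible relative to the mean and the
// remaining growth is advanced deterministically to keep event counts
// bounded.
// [[Rcpp::export]]
NumericVector bd_gillespie(double atma, NumericVector times, double birth,
                           double death, bool condition,
                           double det_threshold = 1e5,
                           int max_attempts = 1000000) {
  int m = times.size();
  NumericVector out(m);
  if (m == 0) return out;
  double s = birth - death;
  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    double t = atma;
    double n = 1.0;
    int i = 0;
    bool reject = false;
    while (i < m) {
      if (n <= 0.0) {
        if (condition && times[0] >= t && i == 0) { reject = true; break; }
        for (; i < m; ++i) out[i] = 0.0;
        break;
      }
      if (n >= det_threshold) {
        for (; i < m; ++i) out[i] = std::floor(n * std::exp(s * (times[i] - t)) + 0.5);
        break;
      }
      double rate = n * (birth + death);
      double dt = R::exp_rand() / rate;
      while (i < m && times[i] < t + dt) { out[i] = n; ++i; }
      t += dt;
      if (R::unif_rand() < birth / (birth + death)) n += 1.0; else n -= 1.0;
    }
    if (!reject) {
      if (condition && out[0] <= 0.0) continue;  // extinct before first sample
      return out;
    }
  }
  stop("conditioned birth-death simulation failed: extinction on every attempt");
}
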