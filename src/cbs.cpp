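#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Circular binary segmentation core: maximal two-sample t statistic over
// all circular arcs of a segment, plus its permutation p-value. The arc
// (i, j] (0-based, half-open on bin indices) is compared against its
// complement; both must hold at least min_width bins. The pooled variance
// of the whole segment is used, so the maximization only needs prefix sums.

static double max_arc_t(const std::vector<double> &s, int n, double sd,
                        int min_width, int *best_i, int *best_j) {
  double tmax = 0.0;
  const double total = s[n];
  for (int i = 0; i <= n - min_width; ++i) {
    int jmax = std::min(n, i + (n - min_width));
    for (int j = i + min_width; j <= jmax; ++j) {
      const int len = j - i;
      const int comp = n - len;
      const double arc = s[j] - s[i];
      const double diff = arc / len - (total - arc) / comp;
      const double t = std::fabs(diff) /
        (sd * std::sqrt(1.0 / len + 1.0 / comp));
      if (t > tmax) {
        tmax = t;
        if (best_i) { *best_i = i; *best_j = j; }
      }
    }
  }
  return tmax;
}

// [[Rcpp::export(name = ".cbs_scan", rng = false)]]
List cbs_scan(NumericVector x, int min_width, int nperm, int seed) {
  const int n = x.size();
  if (n < 2 * min_width) {
    return List::create(_["t"] = 0.0, _["i"] = -1, _["j"] = -1, _["p"] = 1.0);
  }
  double mean = 0.0;
  for (int k = 0; k < n; ++k) mean += x[k];
  mean /= n;
  double ss = 0.0;
  for (int k = 0; k < n; ++k) ss += (x[k] - mean) * (x[k] - mean);
  const double sd = std::sqrt(ss / (n - 1));
  if (sd <= 0.0) {
    return List::create(_["t"] = 0.0, _["i"] = -1, _["j"] = -1, _["p"] = 1.0);
  }
  std::vector<double> s(n + 1, 0.0);
  for (int k = 0; k < n; ++k) s[k + 1] = s[k] + x[k];

  int bi = -1, bj = -1;
  const double tobs = max_arc_t(s, n, sd, min_width, &bi, &bj);

  // permutation null; own deterministic generator seeded from R
  std::vector<double> xp(x.begin(), x.end());
  std::mt19937 rng((unsigned int)seed);
  int exceed = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      std::uniform_int_distribution<int> pick(0, k);
      std::swap(xp[k], xp[pick(rng)]);
    }
    std::vector<double> sp(n + 1, 0.0);
    for (int k = 0; k < n; ++k) sp[k + 1] = sp[k] + xp[k];
    if (max_arc_t(sp, n, sd, min_width, nullptr, nullptr) >= tobs) ++exceed;
    // early exit: p-value already far above any usual alpha
    if (exceed > nperm / 5) { exceed = nperm; break; }
  }
  const double pval = (1.0 + exceed) / (1.0 + nperm);
  return List::create(_["t"] = tobs, _["i"] = bi, _["j"] = bj, _["p"] = pval);
}
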