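#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Max circular two-sample t statistic over all arcs (i, j] of x, and its
// permutation null. The arc-vs-complement statistic is
//   T = (mean_arc - mean_rest) / (s * sqrt(1/k + 1/(n-k)))
// with s the global standard deviation; the scan is O(n^2) per evaluation,
// which is why it lives in compiled code (as in the classic CBS
// implementations).

static void max_arc_stat(const std::vector<double>& cs, int n, double s,
                         double& best, int& bi, int& bj) {
  best = 0.0; bi = 0; bj = 0;
  double total = cs[n];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j <= n; ++j) {
      int k = j - i;
      if (n - k < 2) break;
      double m1 = (cs[j] - cs[i]) / k;
      double m2 = (total - cs[j] + cs[i]) / (n - k);
      double t = std::fabs(m1 - m2) / (s * std::sqrt(1.0 / k + 1.0 / (n - k)));
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int n_perm, double alpha, int seed) {
  int n = x.size();
  if (n < 4) return List::create(_["p"] = 1.0, _["i"] = 0, _["j"] = 0,
                                 _["stat"] = 0.0);
  double sd = Rcpp::sd(x);
  if (sd <= 0) return List::create(_["p"] = 1.0, _["i"] = 0, _["j"] = 0,
                                   _["stat"] = 0.0);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  double obs; int bi, bj;
  max_arc_stat(cs, n, sd, obs, bi, bj);

  // permutation p-value with early exit once significance is impossible
  std::vector<double> xs(x.begin(), x.end());
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int exceed = 0;
  int needed = (int)std::ceil(alpha * (n_perm + 1));
  int done = 0;
  for (int p = 0; p < n_perm; ++p) {
    std::shuffle(xs.begin(), xs.end(), rng);
    std::vector<double> pcs(n + 1, 0.0);
    for (int i = 0; i < n; ++i) pcs[i + 1] = pcs[i] + xs[i];
    double pb; int pi, pj;
    max_arc_stat(pcs, n, sd, pb, pi, pj);
    if (pb >= obs) ++exceed;
    ++done;
    if (exceed >= needed) break; // cannot be significant any more
  }
  double pval = (exceed + 1.0) / (done + 1.0);
  return List::create(_["p"] = pval, _["i"] = bi, _["j"] = bj,
                      _["stat"] = obs);
}
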