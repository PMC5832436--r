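#include <Rcpp.h>
using namespace Rcpp;

// Max two-sample t statistic over all circular arcs of x, with every
// resulting piece (arc, left flank, right flank) at least min_bins long
// (zero-length flanks allowed). Writes the best arc [i, j) into *bi, *bj.
static double max_arc_t(const std::vector<double>& x, int min_bins,
                        int* bi, int* bj) {
  int n = (int)x.size();
  double best = -1.0;
  *bi = -1; *bj = -1;
  if (n < 2 * min_bins) return 0.0;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    Q[t + 1] = Q[t] + x[t] * x[t];
  }
  for (int i = 0; i <= n - min_bins; ++i) {
    if (i != 0 && i < min_bins) continue;
    for (int j = i + min_bins; j <= n; ++j) {
      if (j != n && n - j < min_bins) continue;
      if (i == 0 && j == n) continue;
      int k = j - i, m = n - k;
      if (m < 1) continue;
      double m1 = (S[j] - S[i]) / k;
      double m2 = (S[n] - S[j] + S[i]) / m;
      double ss1 = (Q[j] - Q[i]) - (double)k * m1 * m1;
      double ss2 = (Q[n] - Q[j] + Q[i]) - (double)m * m2 * m2;
      double s2 = (ss1 + ss2) / std::max(n - 2, 1);
      double denom = s2 * (1.0 / k + 1.0 / m);
      double t;
      if (denom <= 1e-300) {
        t = (std::fabs(m1 - m2) < 1e-12) ? 0.0 : 1e6;
      } else {
        t = std::fabs(m1 - m2) / std::sqrt(denom);
      }
      if (t > best) { best = t; *bi = i; *bj = j; }
    }
  }
  return best < 0 ? 0.0 : best;
}

// Best arc split of a segment plus its permutation p-value.
// Early-exits once the split can no longer reach p < alpha. Uses R's RNG.
// [[Rcpp::export(name = ".cbs_test")]]
List cbs_test(NumericVector x, int min_bins, int n_perm, double alpha) {
  std::vector<double> v(x.begin(), x.end());
  int bi, bj;
  double t_obs = max_arc_t(v, min_bins, &bi, &bj);
  if (bi < 0) {
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["stat"] = 0.0, _["p"] = 1.0);
  }
  std::vector<double> perm(v);
  int n = (int)perm.size();
  int exceed = 0, done = 0;
  int stop_at = (int)std::ceil(alpha * n_perm);  // p >= alpha is then certain
  int pi, pj;
  for (int b = 0; b < n_perm; ++b) {
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(perm[t], perm[u]);
    }
    double tp = max_arc_t(perm, min_bins, &pi, &pj);
    ++done;
    if (tp >= t_obs) {
      if (++exceed >= stop_at) break;
    }
  }
  double p = (double)exceed / (double)done;
  return List::create(_["i"] = bi, _["j"] = bj,
                      _["stat"] = t_obs, _["p"] = p);
}
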