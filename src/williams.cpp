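#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted pool-adjacent-violators under a nondecreasing constraint;
// returns the isotonic (amalgamated) estimate of the LAST level's mean.
static double pava_top(const std::vector<double>& m,
                       const std::vector<double>& w) {
  const int k = (int)m.size();
  std::vector<double> val(k), wt(k);
  std::vector<int> sz(k);
  int nb = 0;
  for (int i = 0; i < k; ++i) {
    val[nb] = m[i]; wt[nb] = w[i]; sz[nb] = 1; ++nb;
    while (nb > 1 && val[nb - 2] > val[nb - 1]) {
      double tw = wt[nb - 2] + wt[nb - 1];
      val[nb - 2] = (wt[nb - 2] * val[nb - 2] + wt[nb - 1] * val[nb - 1]) / tw;
      wt[nb - 2] = tw; sz[nb - 2] += sz[nb - 1]; --nb;
    }
  }
  return val[nb - 1];
}

// Williams-type trend statistic in the "up" direction:
// (isotonic amalgamated mean at the top treatment level - anchor mean) /
// sqrt(s2 * (1/n_top + 1/n_anchor)), s2 the pooled within-level variance.
// level codes: 0 = anchor (t = 0), 1..K ordered treatment levels.
static double williams_stat_dir(const double* y, const int* level, int n,
                                int K, int sign) {
  std::vector<double> sum(K + 1, 0.0), ssq(K + 1, 0.0);
  std::vector<int> cnt(K + 1, 0);
  for (int i = 0; i < n; ++i) {
    double v = sign * y[i];
    sum[level[i]] += v; ssq[level[i]] += v * v; ++cnt[level[i]];
  }
  double ss = 0.0; int df = 0;
  std::vector<double> mean(K + 1);
  for (int l = 0; l <= K; ++l) {
    mean[l] = sum[l] / cnt[l];
    ss += ssq[l] - sum[l] * sum[l] / cnt[l];
    df += cnt[l] - 1;
  }
  double s2 = df > 0 ? ss / df : 0.0;
  std::vector<double> tm(mean.begin() + 1, mean.end());
  std::vector<double> tw(K);
  for (int l = 1; l <= K; ++l) tw[l - 1] = (double)cnt[l];
  double top = pava_top(tm, tw);
  double diff = top - mean[0];
  double se = std::sqrt(s2 * (1.0 / cnt[K] + 1.0 / cnt[0]));
  if (se <= 0.0 || !std::isfinite(se)) {
    if (std::fabs(diff) < 1e-300) return 0.0;
    return diff > 0 ? 1e300 : -1e300;
  }
  return diff / se;
}

// Permutation p value for one response vector. Both directions are tested;
// one-sided p values use the add-one correction; the two-sided p is
// min(1, 2 * min(p_up, p_down)).
static void williams_perm_one(const double* y0, const int* level, int n,
                              int K, int nperm,
                              double& p_two, double& stat_up,
                              double& stat_down) {
  stat_up = williams_stat_dir(y0, level, n, K, +1);
  stat_down = williams_stat_dir(y0, level, n, K, -1);
  std::vector<double> y(y0, y0 + n);
  int ge_up = 0, ge_down = 0;
  for (int b = 0; b < nperm; ++b) {
    // Fisher-Yates shuffle driven by R's RNG (respects set.seed)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    double su = williams_stat_dir(y.data(), level, n, K, +1);
    double sd = williams_stat_dir(y.data(), level, n, K, -1);
    if (su >= stat_up) ++ge_up;
    if (sd >= stat_down) ++ge_down;
  }
  double p_up = (1.0 + ge_up) / (nperm + 1.0);
  double p_down = (1.0 + ge_down) / (nperm + 1.0);
  double p = 2.0 * std::min(p_up, p_down);
  p_two = p < 1.0 ? p : 1.0;
}

// [[Rcpp::export(name = ".williamsPermMatrix")]]
NumericMatrix williamsPermMatrix(NumericMatrix Y, IntegerVector level,
                                 int nlevels, int nperm) {
  const int np = Y.nrow(), n = Y.ncol(), K = nlevels - 1;
  if (level.size() != n) stop("level annotation must match columns");
  if (K < 2) stop("need >= 2 ordered levels beyond the anchor");
  NumericMatrix out(np, 3);
  colnames(out) = CharacterVector::create("p", "stat_up", "stat_down");
  std::vector<int> lv(level.begin(), level.end());
  std::vector<double> row(n);
  GetRNGstate();
  for (int i = 0; i < np; ++i) {
    for (int j = 0; j < n; ++j) row[j] = Y(i, j);
    double p, su, sd;
    williams_perm_one(row.data(), lv.data(), n, K, nperm, p, su, sd);
    out(i, 0) = p; out(i, 1) = su; out(i, 2) = sd;
  }
  PutRNGstate();
  return out;
}

// [[Rcpp::export(name = ".williamsStat")]]
double williamsStat(NumericVector y, IntegerVector level, int nlevels,
                    int sign) {
  std::vector<int> lv(level.begin(), level.end());
  return williams_stat_dir(REAL(y), lv.data(), y.size(), nlevels - 1, sign);
}
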