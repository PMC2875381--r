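#include <Rcpp.h>
using namespace Rcpp;

// Max |t| over circular arcs of x: cut points 0 <= i < j <= n define the arc
// x[i+1..j] versus its (wrapping) complement; pooled two-sample t.
// Arc and complement must each hold at least min_width probes.
// Returns (i, j, |t|) with 0-based cut points (0 and n are the boundaries).
static void max_arc_t_core(const double *x, int n, int min_width,
                           int &best_i, int &best_j, double &best_t) {
  std::vector<double> S(n + 1, 0.0), SS(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    SS[k + 1] = SS[k] + x[k] * x[k];
  }
  best_i = -1; best_j = -1; best_t = 0.0;
  if (n < 2 * min_width) return;
  const double tot = S[n], totSS = SS[n];
  for (int i = 0; i <= n - 1; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i, m = n - k;
      if (k < min_width || m < min_width) continue;
      double Sa = S[j] - S[i];
      double SSa = SS[j] - SS[i];
      double Sc = tot - Sa, SSc = totSS - SSa;
      double diff = Sa / k - Sc / m;
      double W = (SSa - Sa * Sa / k) + (SSc - Sc * Sc / m);
      double t;
      if (n > 2 && W > 1e-12) {
        double s2 = W / (n - 2);
        t = std::fabs(diff) / std::sqrt(s2 * (1.0 / k + 1.0 / m));
      } else {
        // degenerate pooled variance: infinite separation if means differ
        t = std::fabs(diff) > 1e-12 ? 1e12 * std::fabs(diff) : 0.0;
      }
      if (t > best_t) { best_t = t; best_i = i; best_j = j; }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_max_arc_t(NumericVector x, int min_width) {
  int i, j; double t;
  max_arc_t_core(x.begin(), x.size(), min_width, i, j, t);
  return NumericVector::create(i, j, t);
}

// Permutation reference for the max-|t| statistic: shuffles x (R RNG, so the
// caller's seed governs) and counts permutations whose max |t| reaches t_obs.
// Stops early once the count exceeds max_exceed (the split is then already
// rejected at the caller's alpha).
// [[Rcpp::export]]
int cpp_perm_exceed(NumericVector x, int min_width, double t_obs,
                    int n_perm, int max_exceed) {
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    int i, j; double t;
    max_arc_t_core(y.data(), n, min_width, i, j, t);
    if (t >= t_obs) {
      if (++count > max_exceed) return count;
    }
  }
  return count;
}
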