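#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernel.
//
// For a sequence x[0..n-1] viewed as a circle, every circular split into
// two arcs is indexed by a pair i < j: arc = x[i..j-1], complement the
// rest. The split statistic is the two-sample t statistic (pooled
// variance) between arc and complement. max_t_split scans all admissible
// arcs in O(n^2) using prefix sums; cbs_perm_p repeats the scan on
// permuted data to get a permutation p-value for the best observed split,
// with early termination once the p-value can no longer fall below alpha.

namespace {

struct Split {
  int i, j;        // arc covers indices [i, j)
  double t;        // |t| of the best split; 0 if none admissible
};

Split max_t_split_core(const double* x, int n, int min_width) {
  Split best = {0, 0, 0.0};
  if (n < 2 * min_width) return best;

  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
  const double tot = S[n], totq = Q[n];

  for (int i = 0; i <= n - min_width; ++i) {
    int jmin = i + min_width;
    int jmax = std::min(n, i + (n - min_width));
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - i;             // arc length
      int m = n - k;             // complement length
      double s1 = S[j] - S[i];
      double s0 = tot - s1;
      double ss1 = Q[j] - Q[i] - s1 * s1 / k;
      double ss0 = (totq - (Q[j] - Q[i])) - s0 * s0 / m;
      double diff = std::fabs(s1 / k - s0 / m);
      double pooled = (ss1 + ss0) / (n - 2);
      double t;
      if (pooled <= 0) {
        // both sides constant: infinitely strong split unless means agree
        if (diff <= 0) continue;
        t = std::numeric_limits<double>::infinity();
      } else {
        t = diff / std::sqrt(pooled * (1.0 / k + 1.0 / m));
      }
      if (t > best.t) {
        best.t = t;
        best.i = i;
        best.j = j;
      }
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export(name = ".cbs_max_t")]]
List cbs_max_t(NumericVector x, int min_width) {
  Split s = max_t_split_core(REAL(x), x.size(), min_width);
  return List::create(_["i"] = s.i, _["j"] = s.j, _["t"] = s.t);
}

// [[Rcpp::export(name = ".cbs_perm_p")]]
double cbs_perm_p(NumericVector x, double t_obs, int n_perm, int min_width,
                  double alpha) {
  int n = x.size();
  std::vector<double> y(REAL(x), REAL(x) + n);
  int exceed = 0;
  // Early stop: once exceed > alpha * n_perm the final p-value must be
  // >= alpha, so the split will be rejected regardless of remaining perms.
  double stop_at = alpha * n_perm;
  int done = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG (respects set.seed in the caller).
    for (int k = n - 1; k > 0; --k) {
      int idx = static_cast<int>(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    Split s = max_t_split_core(y.data(), n, min_width);
    if (s.t >= t_obs) ++exceed;
    ++done;
    if (exceed > stop_at) break;
  }
  // Permutation p-value with the +1 convention.
  return (exceed + 1.0) / (done + 1.0);
}
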