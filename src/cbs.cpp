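#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// CBS arc search. Arcs follow the circular convention: arc (i, j) is
// probes i+1..j and its complement wraps around; the two-sample statistic
// is symmetric in the groups, so scanning all 0 <= i < j <= n covers every
// circular split.
//
// For a fixed multiset of values the pooled-variance t is strictly
// monotone in the between-group sum of squares
//   D(i, j) = (n*A - m*S)^2 / (n*m*(n-m)),
// where A is the arc sum, S the segment sum, m the arc length, via
//   t^2 = (n-2) * D / (SS_tot - D),
// SS_tot being the total (permutation-invariant) sum of squares about the
// segment mean. Maximizing or thresholding t therefore reduces to prefix
// sums of the values alone, which is what makes the permutation test cheap.

struct ArcBest {
  int i, j;
  double D;
};

// exhaustive max-D search; ties broken by the lexicographically smallest
// (i, j); inv_mm[m] caches 1/(m*(n-m))
static ArcBest max_arc_D(const std::vector<double> &S, int n, int min_probes,
                         const std::vector<double> &inv_mm) {
  ArcBest best = {-1, -1, -1.0};
  const double total = S[n];
  for (int i = 0; i <= n - min_probes; ++i) {
    const int j_lo = i + min_probes;
    const int j_hi = std::min(n, i + n - min_probes);
    for (int j = j_lo; j <= j_hi; ++j) {
      const int m = j - i;
      const double u = n * (S[j] - S[i]) - m * total;
      const double D = u * u * inv_mm[m] / n;
      if (D > best.D) {
        best.D = D;
        best.i = i;
        best.j = j;
      }
    }
  }
  return best;
}

static void prefix_sum(const std::vector<double> &x, std::vector<double> &S) {
  const int n = (int)x.size();
  S.assign(n + 1, 0.0);
  for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
}

static double total_ss(const std::vector<double> &x) {
  const int n = (int)x.size();
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += x[k];
  const double mean = s / n;
  double ss = 0.0;
  for (int k = 0; k < n; ++k) {
    const double d = x[k] - mean;
    ss += d * d;
  }
  return ss;
}

static std::vector<double> make_inv_mm(int n) {
  std::vector<double> inv_mm(n + 1, 0.0);
  for (int m = 1; m < n; ++m) inv_mm[m] = 1.0 / ((double)m * (n - m));
  return inv_mm;
}

// [[Rcpp::export]]
List cbs_max_t(NumericVector x, int min_probes) {
  const int n = x.size();
  if (n < 2 * min_probes || n <= 2) {
    return List::create(_["i"] = -1, _["j"] = -1, _["t"] = -1.0);
  }
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> S;
  prefix_sum(xv, S);
  const std::vector<double> inv_mm = make_inv_mm(n);
  const ArcBest best = max_arc_D(S, n, min_probes, inv_mm);
  const double ss_tot = total_ss(xv);
  double t;
  if (ss_tot <= 0.0 || best.D <= 0.0) {
    t = 0.0;
  } else if (ss_tot - best.D <= 1e-9 * ss_tot) {
    t = std::numeric_limits<double>::infinity();  // zero within-group variance
  } else {
    t = std::sqrt((n - 2) * best.D / (ss_tot - best.D));
  }
  return List::create(_["i"] = best.i, _["j"] = best.j, _["t"] = t);
}

// Permutation exceedance count for the max-t statistic. Permutes x with
// Fisher-Yates driven by R's RNG (deterministic under set.seed) and counts
// permutations whose max arc t reaches t_obs, i.e. whose max D reaches the
// equivalent threshold. Two early exits: within a permutation the scan
// aborts at the first qualifying arc, and the permutation loop stops once
// the count exceeds max_exceed (the split is already rejected).
// [[Rcpp::export]]
int cbs_perm_exceed(NumericVector x, double t_obs, int n_perm, int min_probes,
                    int max_exceed) {
  const int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  const double ss_tot = total_ss(y);
  double D_thr;
  if (t_obs <= 0.0 || ss_tot <= 0.0) {
    D_thr = -1.0;  // every permutation trivially reaches a zero statistic
  } else if (!std::isfinite(t_obs)) {
    D_thr = ss_tot * (1.0 - 1e-9);  // needs zero within-group variance
  } else {
    const double t2 = t_obs * t_obs;
    D_thr = ss_tot * t2 / ((n - 2) + t2);
  }
  const std::vector<double> inv_mm = make_inv_mm(n);
  const double thr_n = D_thr * n;  // compare u^2 * inv_mm[m] against this
  std::vector<double> S;
  int exceed = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int r = (int)std::floor(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(y[k], y[r]);
    }
    bool hit = (D_thr < 0.0);
    if (!hit) {
      prefix_sum(y, S);
      const double total = S[n];
      for (int i = 0; i <= n - min_probes && !hit; ++i) {
        const int j_lo = i + min_probes;
        const int j_hi = std::min(n, i + n - min_probes);
        const double Si = S[i];
        for (int j = j_lo; j <= j_hi; ++j) {
          const int m = j - i;
          const double u = n * (S[j] - Si) - m * total;
          if (u * u * inv_mm[m] >= thr_n) {
            hit = true;
            break;
          }
        }
      }
    }
    if (hit && ++exceed > max_exceed) return exceed;
  }
  return exceed;
}
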