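#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <cmath>
using namespace Rcpp;

// Exact permutation machinery for the Spearman rank-correlation screen.
// All enumeration is over std::next_permutation so multiset inputs (tied
// ranks) visit each distinct arrangement exactly once.

// Frequency table of S = sum_i (p_i - i)^2 over all n! permutations p of
// 1..n.  S determines r_s for tie-free ranks via r = 1 - 6S/(n^3 - n).
// [[Rcpp::export(name = ".null_sumdsq_counts")]]
NumericVector null_sumdsq_counts(int n) {
  if (n < 1 || n > 10)
    stop("full enumeration supported for 1 <= n <= 10 (got %d)", n);
  const int maxs = n * (n * n - 1) / 3;
  std::vector<double> counts(maxs + 1, 0.0);
  std::vector<int> p(n);
  std::iota(p.begin(), p.end(), 0);
  do {
    int s = 0;
    for (int i = 0; i < n; ++i) {
      const int d = p[i] - i;
      s += d * d;
    }
    counts[s] += 1.0;
  } while (std::next_permutation(p.begin(), p.end()));
  return wrap(counts);
}

static inline double col_mean(const NumericVector& x) {
  return std::accumulate(x.begin(), x.end(), 0.0) / x.size();
}

static inline double col_sd_pop(const NumericVector& x, double m) {
  double s = 0.0;
  for (double v : x) s += (v - m) * (v - m);
  return std::sqrt(s / x.size());
}

// Exact two-sided tail of |r| under permutation of the (possibly tied) rank
// multiset xr against fixed ranks yr.  Returns c(#{|r| >= |r_obs|}, total).
// [[Rcpp::export(name = ".tied_null_tail")]]
NumericVector tied_null_tail(NumericVector xr, NumericVector yr, double r_obs) {
  const int n = xr.size();
  if (n != yr.size()) stop("rank vectors differ in length");
  if (n < 3 || n > 10) stop("tied enumeration supported for 3 <= n <= 10");
  std::vector<double> x(xr.begin(), xr.end());
  std::sort(x.begin(), x.end());
  const double mx = col_mean(xr), my = col_mean(yr);
  const double sx = col_sd_pop(xr, mx), sy = col_sd_pop(yr, my);
  if (sx == 0.0 || sy == 0.0) stop("zero-variance rank vector");
  const double thr = std::fabs(r_obs) - 1e-9;
  double hits = 0.0, total = 0.0;
  do {
    double sxy = 0.0;
    for (int i = 0; i < n; ++i) sxy += x[i] * yr[i];
    const double r = (sxy / n - mx * my) / (sx * sy);
    if (std::fabs(r) >= thr) hits += 1.0;
    total += 1.0;
  } while (std::next_permutation(x.begin(), x.end()));
  return NumericVector::create(hits, total);
}

// Rank-reassignment planting: the permutation v of 1..n whose Spearman
// correlations with the K rank columns of R come closest (least squares)
// to the targets t.  Exhaustive over n! arrangements, n <= 10.
// [[Rcpp::export(name = ".best_rank_plant")]]
NumericVector best_rank_plant(NumericMatrix R, NumericVector t) {
  const int n = R.nrow(), K = R.ncol();
  if (K != t.size()) stop("one target per rank column required");
  if (n < 3 || n > 10) stop("exhaustive planting supported for 3 <= n <= 10");
  const double mv = (n + 1) / 2.0;
  const double sv = std::sqrt((n * (double)n - 1.0) / 12.0);
  std::vector<double> mk(K), sk(K);
  for (int k = 0; k < K; ++k) {
    NumericVector col = R(_, k);
    mk[k] = col_mean(col);
    sk[k] = col_sd_pop(col, mk[k]);
    if (sk[k] == 0.0) stop("zero-variance propensity rank column");
  }
  std::vector<double> Rf(n * K);  // column-major copy for the hot loop
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) Rf[k * n + i] = R(i, k);
  std::vector<double> v(n);
  std::iota(v.begin(), v.end(), 1.0);
  std::vector<double> best(v);
  double best_sse = R_PosInf;
  do {
    double sse = 0.0;
    for (int k = 0; k < K; ++k) {
      double sxy = 0.0;
      const double* col = &Rf[k * n];
      for (int i = 0; i < n; ++i) sxy += v[i] * col[i];
      const double r = (sxy / n - mv * mk[k]) / (sv * sk[k]);
      const double d = r - t[k];
      sse += d * d;
    }
    if (sse < best_sse - 1e-15) {
      best_sse = sse;
      best = v;
    }
  } while (std::next_permutation(v.begin(), v.end()));
  return wrap(best);
}
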