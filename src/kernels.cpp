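#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Counter-free per-gene RNG streams.  Each (seed, gene, batch) triple maps to
// an independent splitmix64 stream, so per-gene Monte-Carlo results do not
// depend on the number of genes or on evaluation order, and successive
// batches add independent draws.

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_seed(uint64_t seed, uint64_t gene, uint64_t batch) {
  uint64_t s = seed * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL;
  s ^= (gene + 1) * 0xFF51AFD7ED558CCDULL;
  s ^= (batch + 1) * 0xC4CEB9FE1A85EC53ULL;
  // scramble once so nearby (seed, gene, batch) triples decorrelate
  uint64_t st = s;
  return splitmix64_next(st);
}

// uniform integer in [0, n) by 128-bit multiply (negligible bias-free enough
// for n << 2^32; n here is a group size, at most a few thousand)
static inline int rand_below(uint64_t &state, int n) {
  return (int)((unsigned __int128)splitmix64_next(state) * (unsigned)n >> 64);
}

// Draw `size` distinct indices from 0..n-1 into pool[0..size-1] by a partial
// Fisher-Yates pass.  The pool may start as any permutation of 0..n-1, so it
// is reused across draws without resetting.
static inline void draw_subset(uint64_t &state, std::vector<int> &pool, int n, int size) {
  for (int t = 0; t < size; ++t) {
    int r = t + rand_below(state, n - t);
    int tmp = pool[t]; pool[t] = pool[r]; pool[r] = tmp;
  }
}

// Structured Monte Carlo for a = 1: enumerate every disease singleton and
// draw B random size-b normal subsets per singleton.  Matrices are passed
// transposed (samples x genes) so each gene's values are contiguous.
// Returns per-(gene, singleton) aggregates so callers can accumulate across
// batches and form conditional Monte-Carlo standard errors:
//   counts  - number of subsets with H(x1 - mean0) = 1  (H(0) = 1)
//   sumdiff - sum of (x1 - mean0)
//   sumsq   - sum of (x1 - mean0)^2
// [[Rcpp::export]]
List cpp_singleton_mc(NumericMatrix x1t, NumericMatrix x0t, int b, int B,
                      double seed, double batch) {
  const int n1 = x1t.nrow(), p = x1t.ncol(), n0 = x0t.nrow();
  IntegerMatrix counts(p, n1);
  NumericMatrix sumdiff(p, n1), sumsq(p, n1);
  std::vector<int> pool(n0);
  const double binv = 1.0 / b;
  for (int j = 0; j < p; ++j) {
    uint64_t st = stream_seed((uint64_t)seed, (uint64_t)j, (uint64_t)batch);
    for (int i = 0; i < n0; ++i) pool[i] = i;
    const double *col0 = &x0t(0, j);
    const double *col1 = &x1t(0, j);
    for (int i = 0; i < n1; ++i) {
      const double x = col1[i];
      int c = 0;
      double sd_ = 0.0, sq_ = 0.0;
      for (int m = 0; m < B; ++m) {
        draw_subset(st, pool, n0, b);
        double s = 0.0;
        for (int t = 0; t < b; ++t) s += col0[pool[t]];
        const double d = x - s * binv;
        if (d >= 0.0) ++c;
        sd_ += d;
        sq_ += d * d;
      }
      counts(j, i) = c;
      sumdiff(j, i) = sd_;
      sumsq(j, i) = sq_;
    }
  }
  return List::create(_["counts"] = counts, _["sumdiff"] = sumdiff,
                      _["sumsq"] = sumsq);
}

// General Monte Carlo over (disease a-subset, normal b-subset) pairs, one
// independent pair per draw, per-gene streams.  Same aggregate outputs,
// collapsed over draws.
// [[Rcpp::export]]
List cpp_pair_mc(NumericMatrix x1t, NumericMatrix x0t, int a, int b,
                 int ndraws, double seed, double batch) {
  const int n1 = x1t.nrow(), p = x1t.ncol(), n0 = x0t.nrow();
  IntegerVector counts(p);
  NumericVector sumdiff(p), sumsq(p);
  std::vector<int> pool1(n1), pool0(n0);
  const double ainv = 1.0 / a, binv = 1.0 / b;
  for (int j = 0; j < p; ++j) {
    uint64_t st = stream_seed((uint64_t)seed, (uint64_t)j, (uint64_t)batch);
    for (int i = 0; i < n1; ++i) pool1[i] = i;
    for (int i = 0; i < n0; ++i) pool0[i] = i;
    const double *col0 = &x0t(0, j);
    const double *col1 = &x1t(0, j);
    int c = 0;
    double sd_ = 0.0, sq_ = 0.0;
    for (int m = 0; m < ndraws; ++m) {
      draw_subset(st, pool1, n1, a);
      double s1 = 0.0;
      for (int t = 0; t < a; ++t) s1 += col1[pool1[t]];
      draw_subset(st, pool0, n0, b);
      double s0 = 0.0;
      for (int t = 0; t < b; ++t) s0 += col0[pool0[t]];
      const double d = s1 * ainv - s0 * binv;
      if (d >= 0.0) ++c;
      sd_ += d;
      sq_ += d * d;
    }
    counts[j] = c;
    sumdiff[j] = sd_;
    sumsq[j] = sq_;
  }
  return List::create(_["counts"] = counts, _["sumdiff"] = sumdiff,
                      _["sumsq"] = sumsq);
}

// Exact pair counting given precomputed subset means (genes x k1 and
// genes x k0): per gene, number of (l, m) pairs with mean1_l - mean0_m >= 0,
// by sorting the normal-side means and binary searching.  Also returns the
// exact mean difference over all pairs.
// [[Rcpp::export]]
List cpp_exact_pairs(NumericMatrix m1, NumericMatrix m0) {
  const int p = m1.nrow(), k1 = m1.ncol(), k0 = m0.ncol();
  NumericVector counts(p), meandiff(p);
  std::vector<double> v0(k0);
  for (int j = 0; j < p; ++j) {
    double s0 = 0.0, s1 = 0.0;
    for (int m = 0; m < k0; ++m) { v0[m] = m0(j, m); s0 += v0[m]; }
    std::sort(v0.begin(), v0.end());
    double c = 0.0;
    for (int l = 0; l < k1; ++l) {
      const double x = m1(j, l);
      s1 += x;
      // count of normal-side means <= x  (ties included: H(0) = 1)
      c += (double)(std::upper_bound(v0.begin(), v0.end(), x) - v0.begin());
    }
    counts[j] = c;
    meandiff[j] = s1 / k1 - s0 / k0;
  }
  return List::create(_["counts"] = counts, _["meandiff"] = meandiff);
}
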