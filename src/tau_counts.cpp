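#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Count pairs i < j with v[i] > v[j] (strict inversions) by bottom-up
// merge sort. Equal elements are not inversions.
static double merge_count_inversions(std::vector<double>& v) {
  const size_t n = v.size();
  std::vector<double> buf(n);
  double inv = 0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo + width < n; lo += 2 * width) {
      size_t mid = lo + width;
      size_t hi = std::min(lo + 2 * width, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (v[i] <= v[j]) {
          buf[k++] = v[i++];
        } else {
          inv += (double)(mid - i);
          buf[k++] = v[j++];
        }
      }
      while (i < mid) buf[k++] = v[i++];
      while (j < hi) buf[k++] = v[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
    }
  }
  return inv;
}

static double tie_pairs(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  double t = 0, run = 1;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) {
      run += 1;
    } else {
      t += run * (run - 1) / 2;
      run = 1;
    }
  }
  t += run * (run - 1) / 2;
  return t;
}

// Pairwise concordance/tie counts for Kendall's tau-b. Returns
// (P, Q, X0, Y0, B): concordant, discordant, tied only in x, tied only in
// y, tied in both. O(n log n): sort by (x, y), count discordant pairs as
// strict inversions of the y sequence, and recover the remaining counts
// from the tie totals (Knight's algorithm).
// [[Rcpp::export]]
NumericVector tau_pair_counts(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  std::vector<size_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  // tie pair totals: within x, within (x, y) jointly, within y
  double tx = 0, txy = 0;
  double runx = 1, runxy = 1;
  std::vector<double> ysorted(n);
  ysorted[0] = y[ord[0]];
  for (R_xlen_t i = 1; i < n; ++i) {
    ysorted[i] = y[ord[i]];
    bool same_x = x[ord[i]] == x[ord[i - 1]];
    if (same_x) {
      runx += 1;
    } else {
      tx += runx * (runx - 1) / 2;
      runx = 1;
    }
    if (same_x && y[ord[i]] == y[ord[i - 1]]) {
      runxy += 1;
    } else {
      txy += runxy * (runxy - 1) / 2;
      runxy = 1;
    }
  }
  tx += runx * (runx - 1) / 2;
  txy += runxy * (runxy - 1) / 2;
  double ty = tie_pairs(std::vector<double>(y.begin(), y.end()));

  // pairs with x[i] < x[j] but y[i] > y[j]: strict inversions of the
  // y-sequence after the (x, y) sort (x-tied pairs are y-sorted, so they
  // contribute none)
  double Q = merge_count_inversions(ysorted);

  double N = (double)n * (n - 1) / 2;
  double X0 = tx - txy;
  double Y0 = ty - txy;
  double P = N - tx - ty + txy - Q;
  return NumericVector::create(P, Q, X0, Y0, txy);
}
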