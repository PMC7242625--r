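#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Agglomerative Ward clustering from singletons down to m clusters.
//
// Merge cost for clusters p, q is the minimum-variance increase
//   n_p * n_q / (n_p + n_q) * ||mean_p - mean_q||^2.
// Ties are broken toward the lowest (p, q) id pair, p < q, where a merged
// cluster keeps the smaller of the two ids (ids start as row indices).
//
// The pairwise cost matrix is kept in full; per-row nearest-neighbor
// caches (over columns q > p) avoid the O(n^2) scan per merge, with rows
// rescanned only when their cached neighbor is invalidated.
//
// Returns a 1-based assignment vector; cluster labels are renumbered 1..m
// in order of each cluster's smallest member row.
// [[Rcpp::export(name = ".ward_agglomerate_cpp")]]
IntegerVector ward_agglomerate_cpp(NumericMatrix data, int m) {
  const int n = data.nrow(), d = data.ncol();
  if (m < 1 || m > n) stop("number of clusters must be in 1..nrow(data)");

  std::vector<double> cent(data.begin(), data.end()); // column-major n x d
  std::vector<double> sz(n, 1.0);
  std::vector<bool> active(n, true);
  std::vector<int> label(n);
  for (int i = 0; i < n; ++i) label[i] = i;

  std::vector<double> cost((size_t)n * n, INF); // symmetric, full storage
  for (int q = 1; q < n; ++q)
    for (int p = 0; p < q; ++p) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = cent[p + (size_t)n * k] - cent[q + (size_t)n * k];
        s += diff * diff;
      }
      double c = 0.5 * s; // n_p = n_q = 1
      cost[p + (size_t)n * q] = c;
      cost[q + (size_t)n * p] = c;
    }

  // nn[p]: column q > p minimizing cost(p, q), lowest q on ties
  std::vector<int> nn(n, -1);
  std::vector<double> mind(n, INF);
  auto rescan = [&](int p) {
    double best = INF;
    int arg = -1;
    for (int q = p + 1; q < n; ++q) {
      if (!active[q]) continue;
      double c = cost[p + (size_t)n * q];
      if (c < best) { best = c; arg = q; }
    }
    mind[p] = best;
    nn[p] = arg;
  };
  for (int p = 0; p < n - 1; ++p) rescan(p);

  for (int step = 0; step < n - m; ++step) {
    int bp = -1;
    double best = INF;
    for (int p = 0; p < n; ++p)
      if (active[p] && mind[p] < best) { best = mind[p]; bp = p; }
    int bq = nn[bp];

    // merge bq into bp (bp < bq keeps the smaller id)
    double np = sz[bp], nq = sz[bq], nsum = np + nq;
    for (int k = 0; k < d; ++k)
      cent[bp + (size_t)n * k] =
        (np * cent[bp + (size_t)n * k] + nq * cent[bq + (size_t)n * k]) / nsum;
    sz[bp] = nsum;
    active[bq] = false;
    mind[bq] = INF;
    for (int i = 0; i < n; ++i) if (label[i] == bq) label[i] = bp;

    for (int r = 0; r < n; ++r) {
      if (!active[r] || r == bp) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = cent[bp + (size_t)n * k] - cent[r + (size_t)n * k];
        s += diff * diff;
      }
      double c = nsum * sz[r] / (nsum + sz[r]) * s;
      cost[bp + (size_t)n * r] = c;
      cost[r + (size_t)n * bp] = c;
    }

    rescan(bp);
    for (int p = 0; p < n; ++p) {
      if (!active[p] || p == bp || p >= n - 1) continue;
      if (nn[p] == bq || nn[p] == bp) {
        rescan(p); // cached neighbor merged away or its cost changed
      } else if (p < bp) {
        double c = cost[p + (size_t)n * bp];
        // adopt the updated bp column when strictly better, or equal with
        // a lower column id (preserves the lowest-(p,q) tie rule)
        if (c < mind[p] || (c == mind[p] && bp < nn[p])) {
          mind[p] = c;
          nn[p] = bp;
        }
      }
    }
  }

  // renumber surviving cluster ids 1..m in order of smallest member
  std::vector<int> newid(n, 0);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int l = label[i];
    if (newid[l] == 0) newid[l] = ++next;
    out[i] = newid[l];
  }
  return out;
}
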