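#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Standard persistence pairing over GF(2) by column reduction.
//
// Cells are given in filtration order (monotone: every cell after its
// boundary). Column j holds the 0-based positions of the boundary cells of
// cell j. Reduction proceeds by decreasing cell dimension ("clearing"): a
// cell paired as a birth by a higher-dimensional column has a provably zero
// reduced column and is skipped. The pairing itself is the classical
// algorithm: add earlier columns sharing the same lowest row until the
// column is empty or its low is unique.
//
// Returns an integer vector `pair` of length n:
//   pair[j] = i  (0-based) if column j is negative and kills the class born
//                at cell i;
//   pair[j] = -1 if cell j is positive (births a class; essential if no
//                later column ever pairs it, i.e. j never appears as a low).

static void add_columns(std::vector<int> &dst, const std::vector<int> &src) {
  std::vector<int> out;
  out.reserve(dst.size() + src.size());
  std::set_symmetric_difference(dst.begin(), dst.end(), src.begin(), src.end(),
                                std::back_inserter(out));
  dst.swap(out);
}

// [[Rcpp::export]]
IntegerVector reduce_boundary_cpp(IntegerVector offsets, IntegerVector entries,
                                  IntegerVector dims) {
  const int n = dims.size();
  IntegerVector pair(n, -1);
  if (n == 0) return pair;

  std::vector<std::vector<int> > cols(n);
  std::vector<int> low_inv(n, -1);   // row -> column with that low
  std::vector<char> cleared(n, 0);

  int max_dim = 0;
  for (int j = 0; j < n; ++j) max_dim = std::max(max_dim, dims[j]);

  for (int d = max_dim; d >= 1; --d) {
    for (int j = 0; j < n; ++j) {
      if (dims[j] != d || cleared[j]) continue;
      std::vector<int> col(entries.begin() + offsets[j],
                           entries.begin() + offsets[j + 1]);
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int other = low_inv[low];
        if (other < 0) break;
        add_columns(col, cols[other]);
      }
      if (!col.empty()) {
        int low = col.back();
        low_inv[low] = j;
        pair[j] = low;
        cleared[low] = 1;  // column `low` reduces to zero; skip it later
        cols[j].swap(col);
      }
    }
  }
  return pair;
}

// Exact bottleneck distance between two finite persistence diagrams.
//
// Each diagram contributes its off-diagonal points plus one virtual diagonal
// partner per point of the other diagram, giving a square bipartite problem
// of size m = n1 + n2. cost(i, j) is the L-inf transport cost (diagonal to
// diagonal costs 0). The distance is the smallest threshold t for which the
// graph {cost <= t} admits a perfect matching; feasibility is tested with
// Kuhn's augmenting-path matching while binary-searching over the sorted
// distinct costs.

static bool try_augment(int u, const std::vector<std::vector<int> > &adj,
                        std::vector<int> &match_right, std::vector<char> &seen) {
  for (size_t k = 0; k < adj[u].size(); ++k) {
    int v = adj[u][k];
    if (seen[v]) continue;
    seen[v] = 1;
    if (match_right[v] < 0 ||
        try_augment(match_right[v], adj, match_right, seen)) {
      match_right[v] = u;
      return true;
    }
  }
  return false;
}

static bool feasible(const NumericMatrix &cost, double t) {
  const int m = cost.nrow();
  std::vector<std::vector<int> > adj(m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      if (cost(i, j) <= t) adj[i].push_back(j);
  std::vector<int> match_right(m, -1);
  for (int i = 0; i < m; ++i) {
    std::vector<char> seen(m, 0);
    if (!try_augment(i, adj, match_right, seen)) return false;
  }
  return true;
}

// [[Rcpp::export]]
double bottleneck_cpp(NumericMatrix cost) {
  const int m = cost.nrow();
  if (m == 0) return 0.0;
  std::vector<double> cand;
  cand.reserve((size_t)m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) cand.push_back(cost(i, j));
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  int lo = 0, hi = (int)cand.size() - 1;
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (feasible(cost, cand[mid])) hi = mid; else lo = mid + 1;
  }
  return cand[lo];
}
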