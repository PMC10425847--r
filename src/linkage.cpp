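#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <limits>
#include <cstdint>
using namespace Rcpp;

// Unweighted average-linkage agglomeration over a condensed distance vector.
//
// Pairs are ordered by the strict key (distance, smaller member-label rank,
// larger member-label rank); label ranks are the 0-based C-locale sort ranks
// of the leaf labels, and a cluster carries the minimum rank over its
// members. The key order is a strict total order satisfying reducibility for
// average linkage, so the nearest-neighbour-chain algorithm below yields the
// same dendrogram as global minimum selection, in Theta(n^2) time, with
// deterministic tie handling.
//
// Returns an hclust-style merge matrix (negative = leaf, positive = earlier
// merge, 1-based) and the merge heights in nondecreasing key order.

struct PairKey {
  double d;
  int lo, hi;
};

static inline bool key_less(const PairKey& a, const PairKey& b) {
  if (a.d != b.d) return a.d < b.d;
  if (a.lo != b.lo) return a.lo < b.lo;
  return a.hi < b.hi;
}

struct MergeRec {
  int rep_a, rep_b;  // leaf representatives (0-based) of the two clusters
  PairKey key;
};

// [[Rcpp::export]]
List avg_linkage_cpp(NumericVector d, int n, IntegerVector label_rank) {
  if (n < 2) stop("need at least two items to cluster");
  const R_xlen_t expected = (R_xlen_t)n * (n - 1) / 2;
  if (d.size() != expected) stop("condensed distance length does not match n");
  for (R_xlen_t i = 0; i < d.size(); ++i)
    if (!R_finite(d[i])) stop("non-finite distance encountered");

  std::vector<double> D((size_t)n * n, 0.0);
  {
    R_xlen_t k = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++k) {
        D[(size_t)i * n + j] = d[k];
        D[(size_t)j * n + i] = d[k];
      }
  }

  std::vector<bool> active(n, true);
  std::vector<int> size(n, 1), minrank(n), rep(n);
  for (int i = 0; i < n; ++i) {
    minrank[i] = label_rank[i];
    rep[i] = i;
  }

  auto pair_key = [&](int i, int j) {
    PairKey k;
    k.d = D[(size_t)i * n + j];
    if (minrank[i] < minrank[j]) { k.lo = minrank[i]; k.hi = minrank[j]; }
    else { k.lo = minrank[j]; k.hi = minrank[i]; }
    return k;
  };

  std::vector<MergeRec> merges;
  merges.reserve(n - 1);
  std::vector<int> chain;
  chain.reserve(n);
  int n_active = n;
  int start = 0;

  while ((int)merges.size() < n - 1) {
    if (chain.empty()) {
      while (!active[start]) ++start;
      chain.push_back(start);
    }
    int top = chain.back();
    int prev = chain.size() >= 2 ? chain[chain.size() - 2] : -1;
    // nearest neighbour of top in key order
    int best = -1;
    PairKey bk{std::numeric_limits<double>::infinity(), 0, 0};
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == top) continue;
      PairKey kk = pair_key(top, k);
      if (best < 0 || key_less(kk, bk)) { best = k; bk = kk; }
    }
    if (best == prev) {
      // reciprocal nearest neighbours: merge top and prev
      chain.pop_back();
      chain.pop_back();
      int i = top, j = prev;
      MergeRec mr;
      mr.rep_a = rep[i]; mr.rep_b = rep[j];
      mr.key = pair_key(i, j);
      merges.push_back(mr);
      // Lance-Williams update, result kept in slot i
      for (int k = 0; k < n; ++k) {
        if (!active[k] || k == i || k == j) continue;
        double dn = (size[i] * D[(size_t)i * n + k] +
                     size[j] * D[(size_t)j * n + k]) /
                    (double)(size[i] + size[j]);
        D[(size_t)i * n + k] = dn;
        D[(size_t)k * n + i] = dn;
      }
      size[i] += size[j];
      if (minrank[j] < minrank[i]) { minrank[i] = minrank[j]; rep[i] = rep[j]; }
      active[j] = false;
      --n_active;
    } else {
      chain.push_back(best);
    }
  }

  // sort merges into global key order (nondecreasing heights)
  std::vector<int> ord(merges.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return key_less(merges[a].key, merges[b].key);
  });

  // rebuild hclust merge codes with union-find over leaves
  std::vector<int> parent(n), node_code(n);
  for (int i = 0; i < n; ++i) { parent[i] = i; node_code[i] = -(i + 1); }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int s = 0; s < n - 1; ++s) {
    const MergeRec& mr = merges[ord[s]];
    int ra = find(mr.rep_a), rb = find(mr.rep_b);
    int ca = node_code[ra], cb = node_code[rb];
    // put the cluster holding the smaller-label leaf first
    merge(s, 0) = ca;
    merge(s, 1) = cb;
    height[s] = mr.key.d;
    parent[rb] = ra;
    node_code[ra] = s + 1;
  }

  return List::create(_["merge"] = merge, _["height"] = height);
}

// Condensed Hamming counts between rows of a binary matrix, via 64-bit
// packing and popcount. Returns a numeric vector of length n(n-1)/2.
// [[Rcpp::export]]
NumericVector binary_hamming_cpp(IntegerMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  const int w = (m + 63) / 64;
  std::vector<uint64_t> bits((size_t)n * w, 0ULL);
  for (int j = 0; j < m; ++j) {
    const int wj = j >> 6, bj = j & 63;
    for (int i = 0; i < n; ++i) {
      if (x(i, j)) bits[(size_t)i * w + wj] |= (1ULL << bj);
    }
  }
  NumericVector out((R_xlen_t)n * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    const uint64_t* bi = &bits[(size_t)i * w];
    for (int j = i + 1; j < n; ++j, ++k) {
      const uint64_t* bj = &bits[(size_t)j * w];
      int h = 0;
      for (int t = 0; t < w; ++t)
        h += __builtin_popcountll(bi[t] ^ bj[t]);
      out[k] = h;
    }
  }
  return out;
}
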