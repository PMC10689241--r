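// Overlap-score adjacency between feature-bin groups: for each ordered
// pair (U, V), the fraction of the k nearest neighbors of points of U --
// neighbors searched within U union V minus the query -- that fall in V.
// Ties in distance break by point index (stable, matching an order()-based
// enumeration).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".si_overlap_cpp")]]
NumericMatrix si_overlap_cpp(NumericMatrix D, IntegerVector bins, int nb,
                             int k) {
  const int n = D.nrow();
  std::vector<std::vector<int>> members(nb);
  for (int i = 0; i < n; ++i) {
    int b = bins[i] - 1;
    if (b >= 0 && b < nb) members[b].push_back(i);
  }
  NumericMatrix A(nb, nb);
  std::vector<std::pair<double, int>> cand;
  for (int a = 0; a < nb; ++a) {
    for (int b = 0; b < nb; ++b) {
      if (a == b || members[a].empty() || members[b].empty()) continue;
      const std::vector<int> &U = members[a], &V = members[b];
      int pool = (int)(U.size() + V.size());
      int kk = std::min(k, pool - 1);
      long hits = 0;
      for (int u : U) {
        cand.clear();
        for (int p : U) if (p != u) cand.push_back({D(u, p), p});
        for (int p : V) cand.push_back({D(u, p), p});
        std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
        for (int j = 0; j < kk; ++j) {
          int idx = cand[j].second;
          // V membership: binary search in the sorted member list
          if (std::binary_search(V.begin(), V.end(), idx)) ++hits;
        }
      }
      A(a, b) = (double)hits / ((double)U.size() * kk);
    }
  }
  return A;
}
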