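// Vietoris-Rips persistent homology (H0-H2) by boundary-matrix reduction
// over Z/2. Dimensions reduce independently (block-diagonal boundary
// matrix): H0 via union-find on the full edge filtration, H1 by reducing
// triangle columns over edge ranks, H2 by reducing tetrahedron columns over
// triangle ranks. Simplex filtration value = max pairwise distance; the
// complex is truncated at `threshold`, and classes still alive there are
// reported with death = Inf (right-censored at the threshold).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent, size;
  int last_merged_size;  // size of the smaller component in the last merge
  UnionFind(int n) : parent(n), size(n, 1), last_merged_size(0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    last_merged_size = std::min(size[a], size[b]);
    parent[a] = b;
    size[b] += size[a];
    return true;
  }
};

// xor-merge of two ascending index vectors (Z/2 column addition)
void symdiff(std::vector<int> &a, const std::vector<int> &b,
             std::vector<int> &tmp) {
  tmp.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) tmp.push_back(a[i++]);
    else if (a[i] > b[j]) tmp.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) tmp.push_back(a[i++]);
  while (j < b.size()) tmp.push_back(b[j++]);
  a.swap(tmp);
}

struct Simplex {
  double filt;
  int v0, v1, v2, v3;  // unused vertices = -1
};

bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.filt != b.filt) return a.filt < b.filt;
  if (a.v0 != b.v0) return a.v0 < b.v0;
  if (a.v1 != b.v1) return a.v1 < b.v1;
  if (a.v2 != b.v2) return a.v2 < b.v2;
  return a.v3 < b.v3;
}

}  // namespace

// [[Rcpp::export(name = ".rips_cpp")]]
List rips_cpp(NumericMatrix dist, int maxdim, double threshold,
              double max_simplices) {
  const int n = dist.nrow();
  if (dist.ncol() != n) stop("distance matrix must be square");
  auto d = [&](int i, int j) { return dist(i, j); };

  // ---- H0: union-find over the full (untruncated) edge filtration ----
  std::vector<Simplex> edges_all;
  edges_all.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges_all.push_back({d(i, j), i, j, -1, -1});
  std::sort(edges_all.begin(), edges_all.end(), simplex_less);

  std::vector<double> h0_death;
  std::vector<int> h0_size;     // points in the component dying at the merge
  {
    UnionFind uf(n);
    for (const auto &e : edges_all)
      if (uf.unite(e.v0, e.v1)) {
        h0_death.push_back(e.filt);
        h0_size.push_back(uf.last_merged_size);
      }
  }
  NumericMatrix bars0(h0_death.size() + 1, 3);
  for (size_t i = 0; i < h0_death.size(); ++i) {
    bars0(i, 0) = 0.0; bars0(i, 1) = h0_death[i]; bars0(i, 2) = h0_size[i];
  }
  bars0(h0_death.size(), 0) = 0.0;
  bars0(h0_death.size(), 1) = R_PosInf;
  bars0(h0_death.size(), 2) = n;

  List out = List::create(_["H0"] = bars0, _["H1"] = R_NilValue,
                          _["H2"] = R_NilValue, _["threshold"] = threshold,
                          _["n_points"] = n);
  if (maxdim < 1) return out;

  // ---- edges within threshold, in filtration order ----
  std::vector<Simplex> edges;
  for (const auto &e : edges_all)
    if (e.filt <= threshold) edges.push_back(e);
  const int ne = (int)edges.size();
  std::unordered_map<int64_t, int> edge_rank;
  edge_rank.reserve(ne * 2);
  for (int r = 0; r < ne; ++r)
    edge_rank[(int64_t)edges[r].v0 * n + edges[r].v1] = r;

  // positive edges: those not merging components (cycle creators)
  std::vector<char> edge_positive(ne, 0);
  {
    UnionFind uf(n);
    for (int r = 0; r < ne; ++r)
      if (!uf.unite(edges[r].v0, edges[r].v1)) edge_positive[r] = 1;
  }

  // sparse neighbor lists (j > i, within threshold)
  std::vector<std::vector<int>> nb(n);
  for (const auto &e : edges) nb[e.v0].push_back(e.v1);
  for (int i = 0; i < n; ++i) std::sort(nb[i].begin(), nb[i].end());

  // ---- triangles ----
  std::vector<Simplex> tris;
  for (int i = 0; i < n; ++i) {
    for (size_t a = 0; a < nb[i].size(); ++a) {
      int j = nb[i][a];
      for (size_t b = a + 1; b < nb[i].size(); ++b) {
        int k = nb[i][b];
        double djk = d(j, k);
        if (djk <= threshold) {
          double f = std::max(djk, std::max(d(i, j), d(i, k)));
          tris.push_back({f, i, j, k, -1});
        }
      }
      if ((double)tris.size() > max_simplices)
        stop("simplex budget exceeded (triangles); reduce subsample or threshold");
    }
  }
  std::sort(tris.begin(), tris.end(), simplex_less);
  const int nt = (int)tris.size();

  // reduce triangle columns over edge ranks
  std::vector<int> owner_e(ne, -1);               // edge rank -> column idx
  std::vector<std::vector<int>> tri_cols(nt);
  std::vector<char> tri_positive(nt, 0);
  std::vector<std::pair<int, int>> h1_pairs;      // (edge rank, tri idx)
  {
    std::vector<int> col, tmp;
    for (int c = 0; c < nt; ++c) {
      const Simplex &t = tris[c];
      col = {edge_rank[(int64_t)t.v0 * n + t.v1],
             edge_rank[(int64_t)t.v0 * n + t.v2],
             edge_rank[(int64_t)t.v1 * n + t.v2]};
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int piv = col.back();
        if (owner_e[piv] < 0) {
          owner_e[piv] = c;
          h1_pairs.push_back({piv, c});
          break;
        }
        symdiff(col, tri_cols[owner_e[piv]], tmp);
      }
      if (col.empty()) tri_positive[c] = 1;
      else tri_cols[c] = col;
    }
  }

  std::vector<double> b1, d1;
  for (const auto &p : h1_pairs) {
    double birth = edges[p.first].filt, death = tris[p.second].filt;
    if (death > birth) { b1.push_back(birth); d1.push_back(death); }
  }
  for (int r = 0; r < ne; ++r)
    if (edge_positive[r] && owner_e[r] < 0) {  // censored loop
      b1.push_back(edges[r].filt); d1.push_back(R_PosInf);
    }
  NumericMatrix bars1(b1.size(), 2);
  for (size_t i = 0; i < b1.size(); ++i) { bars1(i, 0) = b1[i]; bars1(i, 1) = d1[i]; }
  out["H1"] = bars1;
  if (maxdim < 2) return out;

  // ---- tetrahedra ----
  std::unordered_map<int64_t, int> tri_rank;
  tri_rank.reserve(nt * 2);
  for (int r = 0; r < nt; ++r)
    tri_rank[((int64_t)tris[r].v0 * n + tris[r].v1) * n + tris[r].v2] = r;

  std::vector<Simplex> tets;
  {
    std::vector<int> common;
    for (int i = 0; i < n; ++i) {
      for (size_t a = 0; a < nb[i].size(); ++a) {
        int j = nb[i][a];
        // common neighbors of i and j, > j
        common.clear();
        std::set_intersection(nb[i].begin(), nb[i].end(),
                              nb[j].begin(), nb[j].end(),
                              std::back_inserter(common));
        for (size_t b = 0; b < common.size(); ++b) {
          int k = common[b];
          if (d(j, k) > threshold) continue;
          for (size_t c = b + 1; c < common.size(); ++c) {
            int l = common[c];
            if (d(j, l) > threshold || d(k, l) > threshold) continue;
            double f = std::max({d(i, j), d(i, k), d(i, l),
                                 d(j, k), d(j, l), d(k, l)});
            tets.push_back({f, i, j, k, l});
          }
        }
        if ((double)tets.size() > max_simplices)
          stop("simplex budget exceeded (tetrahedra); reduce subsample or threshold");
      }
    }
  }
  std::sort(tets.begin(), tets.end(), simplex_less);
  const int nq = (int)tets.size();

  std::vector<int> owner_t(nt, -1);
  std::vector<std::vector<int>> tet_cols(nq);
  std::vector<std::pair<int, int>> h2_pairs;  // (tri rank, tet idx)
  std::vector<char> tri_paired(nt, 0);
  {
    std::vector<int> col, tmp;
    for (int c = 0; c < nq; ++c) {
      const Simplex &t = tets[c];
      col = {tri_rank[((int64_t)t.v0 * n + t.v1) * n + t.v2],
             tri_rank[((int64_t)t.v0 * n + t.v1) * n + t.v3],
             tri_rank[((int64_t)t.v0 * n + t.v2) * n + t.v3],
             tri_rank[((int64_t)t.v1 * n + t.v2) * n + t.v3]};
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int piv = col.back();
        if (owner_t[piv] < 0) {
          owner_t[piv] = c;
          h2_pairs.push_back({piv, c});
          tri_paired[piv] = 1;
          break;
        }
        symdiff(col, tet_cols[owner_t[piv]], tmp);
      }
      if (!col.empty()) tet_cols[c] = col;
    }
  }

  std::vector<double> b2, d2;
  for (const auto &p : h2_pairs) {
    double birth = tris[p.first].filt, death = tets[p.second].filt;
    if (death > birth) { b2.push_back(birth); d2.push_back(death); }
  }
  for (int r = 0; r < nt; ++r)
    if (tri_positive[r] && !tri_paired[r]) {  // censored cavity
      b2.push_back(tris[r].filt); d2.push_back(R_PosInf);
    }
  NumericMatrix bars2(b2.size(), 2);
  for (size_t i = 0; i < b2.size(); ++i) { bars2(i, 0) = b2[i]; bars2(i, 1) = d2[i]; }
  out["H2"] = bars2;
  return out;
}
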