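#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Edge {
  double w;
  int i, j;   // i < j
};

bool edge_less(const Edge &a, const Edge &b) {
  if (a.w != b.w) return a.w < b.w;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) {
    for (int k = 0; k < n; ++k) parent[k] = k;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return false;
    parent[ra] = rb;
    return true;
  }
};

// symmetric difference of two sorted index vectors (Z/2 column addition)
std::vector<int> sym_diff(const std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

} // namespace

// Zeroth-order persistence: minimum-spanning-tree merge heights via Kruskal
// on edges sorted by (weight, lexicographic endpoints). Returns the N-1
// finite bars (birth 0) with their merging-edge endpoints (1-based).
// [[Rcpp::export]]
DataFrame cpp_h0_persistence(NumericMatrix dist) {
  int n = dist.nrow();
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back({dist(i, j), i, j});
  std::sort(edges.begin(), edges.end(), edge_less);
  UnionFind uf(n);
  std::vector<double> deaths;
  std::vector<int> ea, eb;
  for (const Edge &e : edges) {
    if (uf.unite(e.i, e.j)) {
      deaths.push_back(e.w);
      ea.push_back(e.i + 1);
      eb.push_back(e.j + 1);
      if ((int)deaths.size() == n - 1) break;
    }
  }
  return DataFrame::create(_["death"] = deaths, _["i"] = ea, _["j"] = eb);
}

// First-order Vietoris-Rips persistence of the clique complex restricted to
// edges <= rmax, simplices to dimension 2. Standard Z/2 boundary-matrix
// column reduction of the triangle boundary over edge rows; simplices are
// ordered by (filtration value, dimension implicit, lexicographic vertex
// tuple). Bars unpaired at rmax are reported with death = rmax and
// truncated = TRUE. Zero-persistence bars are dropped.
// [[Rcpp::export]]
DataFrame cpp_h1_persistence(NumericMatrix dist, double rmax) {
  int n = dist.nrow();
  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= rmax) edges.push_back({dist(i, j), i, j});
  std::sort(edges.begin(), edges.end(), edge_less);
  int ne = edges.size();

  // edge index lookup
  std::vector<std::vector<int>> eidx(n, std::vector<int>(n, -1));
  for (int k = 0; k < ne; ++k) {
    eidx[edges[k].i][edges[k].j] = k;
    eidx[edges[k].j][edges[k].i] = k;
  }

  // MST edges are H0-negative; the rest create cycles (H1-positive)
  UnionFind uf(n);
  std::vector<bool> positive(ne, false);
  for (int k = 0; k < ne; ++k)
    if (!uf.unite(edges[k].i, edges[k].j)) positive[k] = true;

  // triangles with filtration = max edge weight, sorted by (filt, lex)
  struct Tri {
    double w;
    int a, b, c;
  };
  std::vector<Tri> tris;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      if (eidx[a][b] < 0) continue;
      for (int c = b + 1; c < n; ++c) {
        if (eidx[a][c] < 0 || eidx[b][c] < 0) continue;
        double w = std::max(dist(a, b), std::max(dist(a, c), dist(b, c)));
        tris.push_back({w, a, b, c});
      }
    }
  std::sort(tris.begin(), tris.end(), [](const Tri &x, const Tri &y) {
    if (x.w != y.w) return x.w < y.w;
    if (x.a != y.a) return x.a < y.a;
    if (x.b != y.b) return x.b < y.b;
    return x.c < y.c;
  });

  std::vector<int> pivot_col(ne, -1);  // edge row -> owning reduced column
  std::vector<std::vector<int>> cols(tris.size());
  std::vector<double> birth, death;
  std::vector<int> ei, ej;
  std::vector<bool> trunc;

  for (size_t t = 0; t < tris.size(); ++t) {
    std::vector<int> col = {eidx[tris[t].a][tris[t].b],
                            eidx[tris[t].a][tris[t].c],
                            eidx[tris[t].b][tris[t].c]};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      if (pivot_col[low] < 0) break;
      col = sym_diff(col, cols[pivot_col[low]]);
    }
    if (!col.empty()) {
      int low = col.back();
      pivot_col[low] = t;
      cols[t] = col;
      double b = edges[low].w, d = tris[t].w;
      if (d > b) {
        birth.push_back(b);
        death.push_back(d);
        ei.push_back(edges[low].i + 1);
        ej.push_back(edges[low].j + 1);
        trunc.push_back(false);
      }
    }
  }
  // positive edges never killed within rmax: truncated bars
  for (int k = 0; k < ne; ++k) {
    if (positive[k] && pivot_col[k] < 0 && rmax > edges[k].w) {
      birth.push_back(edges[k].w);
      death.push_back(rmax);
      ei.push_back(edges[k].i + 1);
      ej.push_back(edges[k].j + 1);
      trunc.push_back(true);
    }
  }
  return DataFrame::create(_["birth"] = birth, _["death"] = death,
                           _["i"] = ei, _["j"] = ej,
                           _["truncated"] = trunc);
}

// Pairwise L1 (cityblock) distances between rows of X and rows of Y.
// [[Rcpp::export]]
NumericMatrix cpp_l1_cross_distance(NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow(), m = Y.nrow(), p = X.ncol();
  if (Y.ncol() != p) stop("descriptor lengths differ");
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += std::abs(X(i, k) - Y(j, k));
      D(i, j) = s;
    }
  }
  return D;
}
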