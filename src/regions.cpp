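#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labelling of a binary mask (values != 0 are
// foreground). connectivity is 4 or 8. Labels are assigned 1..K in
// row-major scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) == 0 || lab(r2, c2) != 0) continue;
          lab(r2, c2) = next;
          q.push(std::make_pair(r2, c2));
        }
      }
    }
  return lab;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// Graph-based region merging on a single intensity image: start from
// single-pixel regions and repeatedly merge 4-adjacent regions whose mean
// intensities differ by less than `threshold` (absolute units), sweeping in
// row-major order until a full pass makes no merge. Deterministic.
// Pixels where valid == 0 stay background (segment 0).
// [[Rcpp::export]]
IntegerMatrix merge_regions_cpp(NumericMatrix intensity, IntegerMatrix valid,
                                double threshold, int max_pass) {
  const int nr = intensity.nrow(), nc = intensity.ncol();
  const int n = nr * nc;
  UnionFind uf(n);
  std::vector<double> sum(n, 0.0);
  std::vector<int> cnt(n, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int i = c * nr + r;
      if (valid(r, c)) { sum[i] = intensity(r, c); cnt[i] = 1; }
    }
  bool merged = true;
  int pass = 0;
  while (merged && pass++ < max_pass) {
    merged = false;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        if (!valid(r, c)) continue;
        const int i = c * nr + r;
        // right and down neighbours cover every 4-adjacent pair once
        for (int k = 0; k < 2; ++k) {
          const int r2 = r + (k == 0 ? 0 : 1), c2 = c + (k == 0 ? 1 : 0);
          if (r2 >= nr || c2 >= nc || !valid(r2, c2)) continue;
          const int j = c2 * nr + r2;
          int a = uf.find(i), b = uf.find(j);
          if (a == b) continue;
          const double ma = sum[a] / cnt[a], mb = sum[b] / cnt[b];
          if (std::fabs(ma - mb) < threshold) {
            uf.unite(a, b);
            const int root = uf.find(a), other = root == a ? b : a;
            sum[root] += sum[other];
            cnt[root] += cnt[other];
            merged = true;
          }
        }
      }
  }
  // relabel roots contiguously in row-major scan order
  std::vector<int> newid(n, 0);
  int next = 0;
  IntegerMatrix seg(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!valid(r, c)) continue;
      const int root = uf.find(c * nr + r);
      if (newid[root] == 0) newid[root] = ++next;
      seg(r, c) = newid[root];
    }
  return seg;
}
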