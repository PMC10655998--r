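#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

static void neighbour_offsets(int connectivity,
                              std::vector<int>& dr, std::vector<int>& dc) {
  // already-visited neighbours under column-major scan order
  dr = {0, -1};
  dc = {-1, 0};
  if (connectivity == 8) {
    dr.push_back(-1); dc.push_back(-1);
    dr.push_back(1); dc.push_back(-1);
  }
}

// Two-pass connected-component labeling of a logical matrix.
// Returns an integer matrix with labels 1..K in raster order, 0 background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  std::vector<int> dr, dc;
  neighbour_offsets(connectivity, dr, dc);

  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      for (size_t k = 0; k < dr.size(); ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // resolve + compact labels in first-appearance (raster) order
  std::vector<int> remap(next + 1, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  return lab;
}

// Seeded region growing: connected components of `dark` are seeds; every
// light-labelled component adjacent (under `connectivity`) to >=1 seed is
// attached to it, and a light component touching several seeds merges them
// into one object. Light components touching no seed are dropped.
// Returns candidate labels 1..K (0 = not part of any candidate).
// [[Rcpp::export]]
IntegerMatrix cpp_grow_candidates(const LogicalMatrix& dark,
                                  const LogicalMatrix& light,
                                  int connectivity) {
  const int nr = dark.nrow(), nc = dark.ncol();
  if (light.nrow() != nr || light.ncol() != nc)
    stop("dark and light masks must share dimensions");
  IntegerMatrix dlab = cpp_label_components(dark, connectivity);
  IntegerMatrix llab = cpp_label_components(light, connectivity);
  int nd = 0, nl = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      nd = std::max(nd, dlab(r, c));
      nl = std::max(nl, llab(r, c));
    }

  std::vector<int> parent(nd + 1);
  for (int i = 0; i <= nd; ++i) parent[i] = i;
  // seed attached to each light component (0 = none yet)
  std::vector<int> light_seed(nl + 1, 0);

  std::vector<int> dr8 = {-1, -1, -1, 0, 0, 1, 1, 1};
  std::vector<int> dc8 = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> dr4 = {-1, 0, 0, 1};
  std::vector<int> dc4 = {0, -1, 1, 0};
  const std::vector<int>& dr = (connectivity == 8) ? dr8 : dr4;
  const std::vector<int>& dc = (connectivity == 8) ? dc8 : dc4;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int d = dlab(r, c);
      if (d == 0) continue;
      for (size_t k = 0; k < dr.size(); ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int l = llab(rr, cc);
        if (l == 0) continue;
        if (light_seed[l] == 0) light_seed[l] = d;
        else uf_union(parent, light_seed[l], d);
      }
    }

  // compact candidate ids over seed roots, raster order of dark labels
  std::vector<int> remap(nd + 1, 0);
  int out = 0;
  for (int i = 1; i <= nd; ++i) {
    int root = uf_find(parent, i);
    if (remap[root] == 0) remap[root] = ++out;
  }

  IntegerMatrix cand(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int d = dlab(r, c);
      if (d > 0) {
        cand(r, c) = remap[uf_find(parent, d)];
      } else {
        int l = llab(r, c);
        if (l > 0 && light_seed[l] > 0)
          cand(r, c) = remap[uf_find(parent, light_seed[l])];
      }
    }
  return cand;
}

// Exact permutation count for the Spearman statistic. With untied ranks the
// correlation is monotone decreasing in S = sum of squared rank differences,
// so the one-sided tail is a count over S. Enumerates all n! permutations.
// direction +1: count permutations with rho >= observed (S <= s_obs);
// direction -1: count permutations with rho <= observed (S >= s_obs).
// [[Rcpp::export]]
double cpp_spearman_tail_count(int n, double s_obs, int direction) {
  if (n < 2 || n > 10) stop("exact enumeration supported for 2 <= n <= 10");
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i + 1;
  double count = 0;
  const double eps = 1e-9;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double d = perm[i] - (i + 1);
      s += d * d;
    }
    if (direction >= 0 ? (s <= s_obs + eps) : (s >= s_obs - eps)) count += 1;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return count;
}
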