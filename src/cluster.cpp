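#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

// Single-linkage clustering at a fixed distance threshold and exact point-set
// diameter. Both are O(n^2) worst case but use the spread axis to prune:
// ion-track point sets are strongly elongated, for which the sweeps are
// near-linear. Coordinates are copied into contiguous buffers up front to
// keep the inner loops cache-friendly.

namespace {

struct Points {
  std::vector<double> x, y, z;
  int n;
  explicit Points(const Rcpp::NumericMatrix &m) : n(m.nrow()) {
    x.resize(n); y.resize(n); z.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = m(i, 0);
      y[i] = m(i, 1);
      z[i] = m(i, 2);
    }
  }
  double range(const std::vector<double> &v) const {
    if (n == 0) return 0.0;
    auto mm = std::minmax_element(v.begin(), v.end());
    return *mm.second - *mm.first;
  }
  // axis with the largest coordinate range: 0 = x, 1 = y, 2 = z
  const std::vector<double> &widest() const {
    const double rx = range(x), ry = range(y), rz = range(z);
    if (ry > rx && ry >= rz) return y;
    if (rz > rx && rz > ry) return z;
    return x;
  }
  double dist2(int i, int j) const {
    const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz;
  }
};

int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

void uf_union(std::vector<int> &parent, std::vector<int> &rank_, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) ++rank_[a];
}

std::vector<int> order_by(const std::vector<double> &key, int n) {
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return key[a] < key[b]; });
  return ord;
}

} // namespace

// Connected components of the proximity graph {(i,j): ||p_i - p_j|| <= d}.
// Labels are 1-based, ordered by the smallest member row index.
// [[Rcpp::export(name = ".sl_cluster_labels")]]
Rcpp::IntegerVector sl_cluster_labels(Rcpp::NumericMatrix coords, double d) {
  const Points p(coords);
  Rcpp::IntegerVector labels(p.n);
  if (p.n == 0) return labels;

  const std::vector<double> &t = p.widest();
  const std::vector<int> ord = order_by(t, p.n);

  std::vector<int> parent(p.n), rank_(p.n, 0);
  std::iota(parent.begin(), parent.end(), 0);

  const double d2 = d * d;
  // pairs farther than d along any one axis cannot be within d overall,
  // so only a trailing window along the sort axis needs exact distances
  for (int ii = 1; ii < p.n; ++ii) {
    const int i = ord[ii];
    const double ti = t[i];
    for (int jj = ii - 1; jj >= 0; --jj) {
      const int j = ord[jj];
      if (ti - t[j] > d) break;
      if (p.dist2(i, j) <= d2) uf_union(parent, rank_, i, j);
    }
  }

  // deterministic labels: order of first appearance by original row index
  std::vector<int> lab(p.n, 0);
  int next = 0;
  for (int i = 0; i < p.n; ++i) {
    const int r = uf_find(parent, i);
    if (lab[r] == 0) lab[r] = ++next;
    labels[i] = lab[r];
  }
  return labels;
}

// Exact maximum pairwise Euclidean distance. The bound
// dist(i,j)^2 <= gap_axial(i,j)^2 + (perpendicular bounding-box diagonal)^2
// prunes pairs that cannot beat the incumbent.
// [[Rcpp::export(name = ".point_set_diameter")]]
double point_set_diameter(Rcpp::NumericMatrix coords) {
  const Points p(coords);
  if (p.n < 2) return 0.0;

  const std::vector<double> &t = p.widest();
  const std::vector<int> ord = order_by(t, p.n);

  double perp2 = 0.0;
  for (const std::vector<double> *v : {&p.x, &p.y, &p.z})
    if (v != &t) perp2 += p.range(*v) * p.range(*v);

  double best2 = p.dist2(ord[0], ord[p.n - 1]); // axial extremes: strong start
  for (int ii = 0; ii < p.n - 1; ++ii) {
    const double ti = t[ord[ii]];
    for (int jj = p.n - 1; jj > ii; --jj) {
      const double gap = t[ord[jj]] - ti;
      if (gap * gap + perp2 <= best2) {
        // no nearer-in-axis pair for this ii can improve; once even the far
        // end fails the bound, later ii (smaller gaps) cannot either
        if (jj == p.n - 1) return std::sqrt(best2);
        break;
      }
      const double s = p.dist2(ord[ii], ord[jj]);
      if (s > best2) best2 = s;
    }
  }
  return std::sqrt(best2);
}
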