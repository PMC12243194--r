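// Low-level raster primitives for grain segmentation: connected components,
// exact Euclidean distance transform, marker-driven watershed flooding and
// binary erosion/dilation with a disk structuring element.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 8-connected component labelling of a logical mask; labels are assigned in
// raster (row-major) order of first encounter, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx / nc, cc = idx % nc;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from each TRUE pixel to the nearest
// FALSE pixel; FALSE pixels get 0. Pixels beyond the image border are not
// treated as background.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d2(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      d2(r, c) = mask(r, c) ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = d2(r, c);
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) d2(r, c) = d[r];
  }
  // rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d2(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) d2(r, c) = std::sqrt(d[c]);
  }
  return d2;
}

struct QNode {
  double prio;
  long long order;
  int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.order > b.order;                        // FIFO tie-break
  }
};

// Marker-based watershed by priority flooding: starting from labelled marker
// pixels, repeatedly claim the unlabelled in-mask neighbour with the lowest
// priority value. Ties resolve by insertion order, making the result
// deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& priority,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long long counter = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({priority(r, c), counter++, r * nc + c});
      }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int r = nd.idx / nc, c = nd.idx % nc;
    int L = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2)) continue;
      lab(r2, c2) = L;
      pq.push({priority(r2, c2), counter++, r2 * nc + c2});
    }
  }
  return lab;
}

static std::vector<std::pair<int,int> > disk_offsets(double radius) {
  std::vector<std::pair<int,int> > off;
  int R = (int)std::floor(radius);
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if (dr * dr + dc * dc <= radius * radius + 1e-9)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      bool all = mask(r, c);
      for (size_t k = 0; all && k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        // outside the image counts as background
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || !mask(r2, c2))
          all = false;
      }
      out(r, c) = all;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      bool any = false;
      for (size_t k = 0; !any && k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && mask(r2, c2))
          any = true;
      }
      out(r, c) = any;
    }
  return out;
}
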