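// Low-level raster operations for the reference segmentation pipeline.
// All functions take R matrices (column-major); pixel (r, c) with r in
// [0, nr), c in [0, nc). Connectivity is 4 or 8.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

static inline void neighbours(int conn, const int*& dr, const int*& dc, int& nn) {
  if (conn == 4) { dr = DR4; dc = DC4; nn = 4; }
  else           { dr = DR8; dc = DC8; nn = 8; }
}

// Connected-component labeling of a binary mask. Labels are assigned in
// column-major scan order (deterministic). Background stays 0.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int conn) {
  if (conn != 4 && conn != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int t = 0; t < nn; ++t) {
          int r2 = rr + dr[t], c2 = cc + dc[t];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale morphological reconstruction by dilation (Vincent 1993,
// hybrid algorithm): geodesic dilation of `marker` under `mask` iterated
// to stability. Requires marker <= mask elementwise (enforced by caller).
// [[Rcpp::export]]
NumericMatrix reconstruct_cpp(NumericMatrix marker, NumericMatrix mask, int conn) {
  if (conn != 4 && conn != 8) stop("connectivity must be 4 or 8");
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc) stop("marker/mask dimension mismatch");
  NumericMatrix J(clone(marker));
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);

  // raster (forward) then anti-raster (backward) passes; queue pixels whose
  // neighbours may still rise after the backward pass
  // forward: scan column-major ascending, use already-visited neighbours
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int t = 0; t < nn; ++t) {
        int r2 = r + dr[t], c2 = c + dc[t];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (c2 < c || (c2 == c && r2 < r))  // already visited this pass
          if (J(r2, c2) > v) v = J(r2, c2);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int t = 0; t < nn; ++t) {
        int r2 = r + dr[t], c2 = c + dc[t];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (c2 > c || (c2 == c && r2 > r))
          if (J(r2, c2) > v) v = J(r2, c2);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      // queue if some neighbour could still be raised by this pixel
      for (int t = 0; t < nn; ++t) {
        int r2 = r + dr[t], c2 = c + dc[t];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if ((c2 > c || (c2 == c && r2 > r)) &&
            J(r2, c2) < J(r, c) && J(r2, c2) < mask(r2, c2)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % nr, c = idx / nr;
    for (int t = 0; t < nn; ++t) {
      int r2 = r + dr[t], c2 = c + dc[t];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (J(r2, c2) < J(r, c) && J(r2, c2) < mask(r2, c2)) {
        double v = J(r, c) < mask(r2, c2) ? J(r, c) : mask(r2, c2);
        if (v > J(r2, c2)) {
          J(r2, c2) = v;
          fifo.push(r2 + c2 * nr);
        }
      }
    }
  }
  return J;
}

// Square min-filter (grayscale erosion with a (2*radius+1)^2 window),
// separable, border handled by replication.
// [[Rcpp::export]]
NumericMatrix erode_min_cpp(NumericMatrix img, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = std::numeric_limits<double>::infinity();
      int lo = std::max(0, r - radius), hi = std::min(nr - 1, r + radius);
      for (int r2 = lo; r2 <= hi; ++r2) if (img(r2, c) < v) v = img(r2, c);
      tmp(r, c) = v;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = std::numeric_limits<double>::infinity();
      int lo = std::max(0, c - radius), hi = std::min(nc - 1, c + radius);
      for (int c2 = lo; c2 <= hi; ++c2) if (tmp(r, c2) < v) v = tmp(r, c2);
      out(r, c) = v;
    }
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012).
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
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

// Exact Euclidean distance transform: distance of each foreground pixel
// to the nearest background pixel (background distance 0).
// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) != 0 ? INF : 0.0;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Marker-based watershed by priority flooding: starting from labeled
// markers, flood the elevation surface upward inside `mask`; each
// unlabeled pixel takes the label of the flooding region that reaches it
// first (lowest elevation; FIFO among equal priorities -> deterministic).
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix elev, IntegerMatrix markers,
                            IntegerMatrix mask, int conn) {
  if (conn != 4 && conn != 8) stop("connectivity must be 4 or 8");
  int nr = elev.nrow(), nc = elev.ncol();
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);
  IntegerMatrix lab(nr, nc);
  struct Node { double e; long long ord; int idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.e != b.e) return a.e > b.e;   // min-heap on elevation
      return a.ord > b.ord;               // FIFO among equals
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long ord = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = markers(r, c);
        pq.push({elev(r, c), ord++, r + c * nr});
      }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int t = 0; t < nn; ++t) {
      int r2 = r + dr[t], c2 = c + dc[t];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) == 0 || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      double e = elev(r2, c2) > nd.e ? elev(r2, c2) : nd.e;
      pq.push({e, ord++, r2 + c2 * nr});
    }
  }
  return lab;
}
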