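// 3D image-processing kernels: connected components, Euclidean distance
// transform, marker-controlled watershed, constrained label dilation and
// flat grayscale morphology. All volumes are column-major with dim = (z, y, x),
// i.e. linear index i = z + nz*(y + ny*x), matching R array storage.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <array>

using namespace Rcpp;

static inline void decode(int i, int nz, int ny, int &z, int &y, int &x) {
  z = i % nz;
  int r = i / nz;
  y = r % ny;
  x = r / ny;
}

static std::vector<std::array<int, 3> > neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        offs.push_back({{dz, dy, dx}});
      }
  return offs;
}

// Connected components of a binary volume; labels assigned in raster-scan
// order of each component's first voxel, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z, y, x;
      decode(cur, nz, ny, z, y, x);
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = zz + nz * (yy + ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// One pass of the 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in voxels) from each foreground voxel to the nearest
// background voxel; exact, separable O(n) transform.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  const double INF = 1e20;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int base = nz * (y + ny * x);
      for (int z = 0; z < nz; ++z) f[z] = g[base + z];
      dt1d(f, d, v, zb, nz);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[z + nz * (y + ny * x)];
      dt1d(f, d, v, zb, ny);
      for (int y = 0; y < ny; ++y) g[z + nz * (y + ny * x)] = d[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[z + nz * (y + ny * x)];
      dt1d(f, d, v, zb, nx);
      for (int x = 0; x < nx; ++x) g[z + nz * (y + ny * x)] = d[x];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Regional maxima of `values` restricted to `mask`, using a Chebyshev window
// of the given radius. Plateau voxels all qualify; the caller merges them by
// connected components to obtain one marker per plateau.
// [[Rcpp::export]]
LogicalVector local_max_cpp(NumericVector values, LogicalVector mask,
                            IntegerVector dim, int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  LogicalVector out(n, false);
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || values[i] <= 0) continue;
    int z, y, x;
    decode(i, nz, ny, z, y, x);
    bool ismax = true;
    for (int dz = -radius; dz <= radius && ismax; ++dz)
      for (int dy = -radius; dy <= radius && ismax; ++dy)
        for (int dx = -radius; dx <= radius && ismax; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (values[zz + nz * (yy + ny * xx)] > values[i]) ismax = false;
        }
    out[i] = ismax;
  }
  return out;
}

struct QItem {
  double value;
  long long order;
  int idx;
};
struct QItemCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;                         // FIFO on ties
  }
};

// Meyer's flooding watershed from labelled markers over `landscape`, restricted
// to `mask`. Voxels reached from two or more distinct labels become watershed
// lines and are left at 0 in the output; everything is deterministic (priority
// ties broken by insertion order).
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector landscape, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<char> inqueue(n, 0);
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  std::priority_queue<QItem, std::vector<QItem>, QItemCmp> pq;
  long long counter = 0;

  for (int i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      labels[i] = markers[i];
      inqueue[i] = 1;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (labels[i] <= 0) continue;
    int z, y, x;
    decode(i, nz, ny, z, y, x);
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = zz + nz * (yy + ny * xx);
      if (mask[j] && !inqueue[j]) {
        inqueue[j] = 1;
        pq.push({landscape[j], counter++, j});
      }
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int i = it.idx;
    if (labels[i] != 0) continue;
    int z, y, x;
    decode(i, nz, ny, z, y, x);
    int found = 0;
    bool conflict = false;
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = zz + nz * (yy + ny * xx);
      int lj = labels[j];
      if (lj > 0) {
        if (found == 0) found = lj;
        else if (found != lj) conflict = true;
      }
    }
    if (conflict) {
      labels[i] = -1; // watershed line
      continue;
    }
    if (found > 0) {
      labels[i] = found;
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = zz + nz * (yy + ny * xx);
        if (mask[j] && !inqueue[j]) {
          inqueue[j] = 1;
          pq.push({landscape[j], counter++, j});
        }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    if (labels[i] < 0) labels[i] = 0;
  return labels;
}

// Conditional dilation: labels grow into unlabelled voxels of `mask` in
// synchronous 6-connected steps until no labelled voxel borders an unlabelled
// mask voxel. Simultaneous claims resolve to the lowest label id; existing
// labels are never overwritten.
// [[Rcpp::export]]
IntegerVector cond_dilate_cpp(IntegerVector labels, LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  std::vector<std::array<int, 3> > offs = neighbor_offsets(6);
  IntegerVector cur = clone(labels);
  std::vector<int> frontier;
  for (int i = 0; i < n; ++i)
    if (mask[i] && cur[i] == 0) frontier.push_back(i);

  bool changed = true;
  std::vector<int> claim(n, 0);
  while (changed) {
    changed = false;
    std::vector<int> next_frontier;
    next_frontier.reserve(frontier.size());
    for (size_t f = 0; f < frontier.size(); ++f) {
      int i = frontier[f];
      int z, y, x;
      decode(i, nz, ny, z, y, x);
      int best = 0;
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int lj = cur[zz + nz * (yy + ny * xx)];
        if (lj > 0 && (best == 0 || lj < best)) best = lj;
      }
      claim[i] = best;
      if (best == 0) next_frontier.push_back(i);
    }
    for (size_t f = 0; f < frontier.size(); ++f) {
      int i = frontier[f];
      if (claim[i] > 0) {
        cur[i] = claim[i];
        claim[i] = 0;
        changed = true;
      }
    }
    frontier.swap(next_frontier);
  }
  return cur;
}

// Display-only label dilation: grow labels into background (no mask) for a
// fixed number of synchronous steps; labels never overwrite each other.
// [[Rcpp::export]]
IntegerVector dilate_labels_cpp(IntegerVector labels, IntegerVector dim,
                                int iterations, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  IntegerVector cur = clone(labels);
  for (int it = 0; it < iterations; ++it) {
    IntegerVector nxt = clone(cur);
    for (int i = 0; i < n; ++i) {
      if (cur[i] != 0) continue;
      int z, y, x;
      decode(i, nz, ny, z, y, x);
      int best = 0;
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int lj = cur[zz + nz * (yy + ny * xx)];
        if (lj > 0 && (best == 0 || lj < best)) best = lj;
      }
      if (best > 0) nxt[i] = best;
    }
    cur = nxt;
  }
  return cur;
}

// Flat grayscale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary structuring element given as k x 3 offsets (z, y, x); voxels whose
// shifted position falls outside the volume are ignored, so constant volumes
// are fixed points.
// [[Rcpp::export]]
NumericVector morph_flat_cpp(NumericVector values, IntegerVector dim,
                             IntegerMatrix offsets, bool dilate) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  const int m = offsets.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int z, y, x;
    decode(i, nz, ny, z, y, x);
    double acc = dilate ? -std::numeric_limits<double>::infinity()
                        : std::numeric_limits<double>::infinity();
    for (int k = 0; k < m; ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      double v = values[zz + nz * (yy + ny * xx)];
      if (dilate) {
        if (v > acc) acc = v;
      } else {
        if (v < acc) acc = v;
      }
    }
    out[i] = acc;
  }
  return out;
}

// Separable 1D convolution along one axis (0 = z, 1 = y, 2 = x) with mirror
// boundary handling; kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector values, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  const int len = (axis == 0) ? nz : (axis == 1 ? ny : nx);
  const int stride = (axis == 0) ? 1 : (axis == 1 ? nz : nz * ny);
  NumericVector out(n);

  const int nlines = n / len;
  std::vector<double> line(len), res(len);
  for (int l = 0; l < nlines; ++l) {
    // base index of this line
    int base;
    if (axis == 0) {
      base = l * nz;
    } else if (axis == 1) {
      int z = l % nz, x = l / nz;
      base = z + nz * ny * x;
    } else {
      base = l; // l = z + nz*y
    }
    for (int t = 0; t < len; ++t) line[t] = values[base + t * stride];
    for (int t = 0; t < len; ++t) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) {
        int p = t + k;
        while (p < 0 || p >= len) {       // mirror, repeated for short lines
          if (p < 0) p = -p - 1;
          if (p >= len) p = 2 * len - p - 1;
        }
        s += line[p] * kernel[k + r];
      }
      res[t] = s;
    }
    for (int t = 0; t < len; ++t) out[base + t * stride] = res[t];
  }
  return out;
}
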