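// Low-level 3D image kernels. All volumes are passed as flat vectors in
// R array order with dim = (nz, ny, nx), i.e. z varies fastest; the linear
// index of voxel (z, y, x) is z + nz * (y + ny * x). Scan order over
// increasing linear index is therefore the (z, y, x) raster order used for
// deterministic label numbering.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static std::vector<std::array<int, 3> > neighbor_offsets(int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3> > offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        std::array<int, 3> o = {{dz, dy, dx}};
        offs.push_back(o);
      }
  return offs;
}

// Connected-component labeling of a binary mask; components are numbered
// from 1 in order of first encounter along the (z, y, x) raster.
// [[Rcpp::export]]
IntegerVector ccl3d_cpp(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// ---- exact anisotropic squared Euclidean distance transform --------------
// Felzenszwalb & Huttenlocher lower-envelope 1D transform, applied per axis
// with the physical sample spacing folded into the parabola width.
static const double DT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  zb[0] = -DT_INF;
  zb[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double num = (f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k]);
      s = num / (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance (um^2) from every voxel to the nearest feature voxel.
// spacing = (dz, dy, dx) in um, matching dims = (nz, ny, nx).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dims,
                         NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (feature.size() != n) stop("feature length does not match dims");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : DT_INF;

  const int nd[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  int maxn = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxn), d(maxn), zb(maxn + 1);
  std::vector<int> v(maxn);

  for (int ax = 0; ax < 3; ++ax) {
    int len = nd[ax];
    if (len < 2) continue;
    double w2 = spacing[ax] * spacing[ax];
    int a1 = (ax == 0) ? 1 : 0;
    int a2 = (ax == 2) ? 1 : 2;
    for (int i1 = 0; i1 < nd[a1]; ++i1) {
      for (int i2 = 0; i2 < nd[a2]; ++i2) {
        R_xlen_t base = (R_xlen_t)i1 * stride[a1] + (R_xlen_t)i2 * stride[a2];
        bool any = false;
        for (int q = 0; q < len; ++q) {
          f[q] = out[base + (R_xlen_t)q * stride[ax]];
          if (f[q] < DT_INF) any = true;
        }
        if (!any) continue;
        dt1d(f, d, v, zb, len, w2);
        for (int q = 0; q < len; ++q)
          out[base + (R_xlen_t)q * stride[ax]] = d[q];
      }
    }
  }
  return out;
}

// ---- seeded watershed (priority flood) -----------------------------------
// Grows seed labels over `mask`, always expanding into the highest-priority
// unlabeled voxel next; ties resolved by insertion order (deterministic).
struct WsEntry {
  double p;
  long long ord;
  R_xlen_t idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.p != b.p) return a.p < b.p;  // max-heap on priority
    return a.ord > b.ord;              // FIFO among equal priorities
  }
};

// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims,
                            int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (priority.size() != n || seeds.size() != n || mask.size() != n)
    stop("input lengths do not match dims");
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  IntegerVector labels = clone(seeds);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long ord = 0;

  // expand each voxel exactly once: seeds here, others on first assignment
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] == 0) continue;
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] || labels[j] != 0) continue;
      WsEntry e = {priority[j], ord++, j, labels[i]};
      pq.push(e);
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (labels[e.idx] != 0) continue;
    labels[e.idx] = e.lab;
    int z = (int)(e.idx % nz);
    int y = (int)((e.idx / nz) % ny);
    int x = (int)(e.idx / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] || labels[j] != 0) continue;
      WsEntry ne = {priority[j], ord++, j, e.lab};
      pq.push(ne);
    }
  }
  return labels;
}

// ---- separable filters ----------------------------------------------------

static void conv1d_lines(std::vector<double>& vol, const int nd[3],
                         const R_xlen_t stride[3], int ax,
                         const std::vector<double>& kernel) {
  int len = nd[ax];
  int r = ((int)kernel.size() - 1) / 2;
  int a1 = (ax == 0) ? 1 : 0;
  int a2 = (ax == 2) ? 1 : 2;
  std::vector<double> line(len), res(len);
  for (int i1 = 0; i1 < nd[a1]; ++i1) {
    for (int i2 = 0; i2 < nd[a2]; ++i2) {
      R_xlen_t base = (R_xlen_t)i1 * stride[a1] + (R_xlen_t)i2 * stride[a2];
      for (int q = 0; q < len; ++q)
        line[q] = vol[base + (R_xlen_t)q * stride[ax]];
      for (int q = 0; q < len; ++q) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int idx = q + j;
          // mirror boundary (half-sample symmetric)
          if (idx < 0) idx = -idx - 1;
          if (idx >= len) idx = 2 * len - idx - 1;
          if (idx < 0) idx = 0;
          if (idx >= len) idx = len - 1;
          acc += kernel[j + r] * line[idx];
        }
        res[q] = acc;
      }
      for (int q = 0; q < len; ++q)
        vol[base + (R_xlen_t)q * stride[ax]] = res[q];
    }
  }
}

// Separable Gaussian blur; sigma = (sz, sy, sx) in voxels, 0 skips an axis.
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector img, IntegerVector dims,
                          NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img length does not match dims");
  const int nd[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  std::vector<double> vol(img.begin(), img.end());
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      sum += k[j + r];
    }
    for (size_t j = 0; j < k.size(); ++j) k[j] /= sum;
    conv1d_lines(vol, nd, stride, ax, k);
  }
  return NumericVector(vol.begin(), vol.end());
}

// Box median filter with per-axis radius (rz, ry, rx); window edge is
// clamped at the volume border.
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector img, IntegerVector dims,
                           IntegerVector radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img length does not match dims");
  int rz = radius[0], ry = radius[1], rx = radius[2];
  if (rz < 0 || ry < 0 || rx < 0) stop("radius must be non-negative");
  NumericVector out(n);
  std::vector<double> win;
  win.reserve((size_t)(2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        win.clear();
        for (int xx = std::max(0, x - rx); xx <= std::min(nx - 1, x + rx); ++xx)
          for (int yy = std::max(0, y - ry); yy <= std::min(ny - 1, y + ry); ++yy)
            for (int zz = std::max(0, z - rz); zz <= std::min(nz - 1, z + rz); ++zz)
              win.push_back(img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)]);
        size_t m = win.size() / 2;
        std::nth_element(win.begin(), win.begin() + m, win.end());
        double med = win[m];
        if (win.size() % 2 == 0) {
          std::nth_element(win.begin(), win.begin() + m - 1, win.end());
          med = 0.5 * (med + win[m - 1]);
        }
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = med;
      }
  return out;
}

// Separable box maximum filter with per-axis radius; used for regional
// maxima detection.
// [[Rcpp::export]]
NumericVector maxfilt3d_cpp(NumericVector img, IntegerVector dims,
                            IntegerVector radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img length does not match dims");
  const int nd[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  std::vector<double> vol(img.begin(), img.end());
  std::vector<double> line, res;
  for (int ax = 0; ax < 3; ++ax) {
    int r = radius[ax];
    if (r <= 0) continue;
    int len = nd[ax];
    int a1 = (ax == 0) ? 1 : 0;
    int a2 = (ax == 2) ? 1 : 2;
    line.assign(len, 0.0);
    res.assign(len, 0.0);
    for (int i1 = 0; i1 < nd[a1]; ++i1)
      for (int i2 = 0; i2 < nd[a2]; ++i2) {
        R_xlen_t base = (R_xlen_t)i1 * stride[a1] + (R_xlen_t)i2 * stride[a2];
        for (int q = 0; q < len; ++q)
          line[q] = vol[base + (R_xlen_t)q * stride[ax]];
        for (int q = 0; q < len; ++q) {
          double m = line[q];
          for (int j = std::max(0, q - r); j <= std::min(len - 1, q + r); ++j)
            if (line[j] > m) m = line[j];
          res[q] = m;
        }
        for (int q = 0; q < len; ++q)
          vol[base + (R_xlen_t)q * stride[ax]] = res[q];
      }
  }
  return NumericVector(vol.begin(), vol.end());
}
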