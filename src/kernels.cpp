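// Voxel-level kernels: mesh voxelization, erosion distance transform,
// connected components, marker watershed, trilinear sampling, Gaussian blur.
// Array convention: R arrays dim (nz, ny, nx), column-major; physical points
// are (x, y, z); spacing/origin vectors are (z, y, x) matching array dims.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t off3(int k, int j, int i, int nz, int ny) {
  return (R_xlen_t)k + (R_xlen_t)j * nz + (R_xlen_t)i * (R_xlen_t)nz * ny;
}

// Crossing x-values of a +x ray at (y0, z0) with triangle (a, b, c).
// Returns true and sets *xhit when the projected point lies strictly inside.
static bool ray_tri_x(const double* A, const double* B, const double* C,
                      double y0, double z0, double* xhit) {
  // 2D orientation tests in (y, z) projection
  double d1 = (B[1] - A[1]) * (z0 - A[2]) - (B[2] - A[2]) * (y0 - A[1]);
  double d2 = (C[1] - B[1]) * (z0 - B[2]) - (C[2] - B[2]) * (y0 - B[1]);
  double d3 = (A[1] - C[1]) * (z0 - C[2]) - (A[2] - C[2]) * (y0 - C[1]);
  bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  if (has_neg && has_pos) return false;
  // plane normal
  double ux = B[0] - A[0], uy = B[1] - A[1], uz = B[2] - A[2];
  double vx = C[0] - A[0], vy = C[1] - A[1], vz = C[2] - A[2];
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  if (std::fabs(nx) < 1e-300) return false;  // parallel to ray
  *xhit = A[0] + (ny * (A[1] - y0) + nz * (A[2] - z0)) / nx;
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double oz = origin[0], oy = origin[1], ox = origin[2];
  int nf = faces.nrow();
  LogicalVector out((R_xlen_t)nz * ny * nx);
  // deterministic sub-voxel jitter avoids exact edge/vertex hits
  double ey = 2.3e-7 * sy, ez = 1.7e-7 * sz;
  // restrict scanning to the mesh bounding box
  double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf,
         bz0 = R_PosInf, bz1 = R_NegInf;
  for (int v = 0; v < verts.nrow(); ++v) {
    bx0 = std::min(bx0, verts(v, 0)); bx1 = std::max(bx1, verts(v, 0));
    by0 = std::min(by0, verts(v, 1)); by1 = std::max(by1, verts(v, 1));
    bz0 = std::min(bz0, verts(v, 2)); bz1 = std::max(bz1, verts(v, 2));
  }
  int k_lo = std::max(0, (int)std::ceil((bz0 - oz) / sz));
  int k_hi = std::min(nz - 1, (int)std::floor((bz1 - oz) / sz));
  int j_lo = std::max(0, (int)std::ceil((by0 - oy) / sy));
  int j_hi = std::min(ny - 1, (int)std::floor((by1 - oy) / sy));
  int i_lo = std::max(0, (int)std::ceil((bx0 - ox) / sx));
  int i_hi = std::min(nx - 1, (int)std::floor((bx1 - ox) / sx));
  std::vector<double> xs;
  for (int k = k_lo; k <= k_hi; ++k) {
    double z0 = oz + k * sz + ez;
    for (int j = j_lo; j <= j_hi; ++j) {
      double y0 = oy + j * sy + ey;
      xs.clear();
      for (int f = 0; f < nf; ++f) {
        int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
        double A[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
        double B[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
        double C[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
        double xh;
        if (ray_tri_x(A, B, C, y0, z0, &xh)) xs.push_back(xh);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      for (int i = i_lo; i <= i_hi; ++i) {
        double xc = ox + i * sx;
        // parity of crossings strictly beyond the voxel center
        size_t n_beyond = xs.end() - std::upper_bound(xs.begin(), xs.end(), xc);
        if (n_beyond % 2 == 1) out[off3(k, j, i, nz, ny)] = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix points, NumericMatrix verts,
                                 IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  LogicalVector out(np);
  // jitter scale from mesh extent
  double ymin = R_PosInf, ymax = R_NegInf, zmin = R_PosInf, zmax = R_NegInf;
  for (int v = 0; v < verts.nrow(); ++v) {
    ymin = std::min(ymin, verts(v, 1)); ymax = std::max(ymax, verts(v, 1));
    zmin = std::min(zmin, verts(v, 2)); zmax = std::max(zmax, verts(v, 2));
  }
  double ey = 2.3e-9 * (ymax - ymin + 1.0), ez = 1.7e-9 * (zmax - zmin + 1.0);
  for (int p = 0; p < np; ++p) {
    double y0 = points(p, 1) + ey, z0 = points(p, 2) + ez, x0 = points(p, 0);
    int parity = 0;
    for (int f = 0; f < nf; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      double A[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
      double B[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
      double C[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
      double xh;
      if (ray_tri_x(A, B, C, y0, z0, &xh) && xh > x0) parity++;
    }
    out[p] = (parity % 2 == 1);
  }
  return out;
}

// Erosion depth per voxel of a labelled (or binary) image. A voxel is peeled
// at depth d when it has a 6-neighbour (or the grid edge) not carrying its
// own label among the not-yet-peeled voxels. Depths saturate at `cap`.
// Returns -1 outside objects.
// [[Rcpp::export]]
IntegerVector cpp_erosion_depth(IntegerVector labels, IntegerVector dims,
                                int cap) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector depth(n, -1);
  std::vector<R_xlen_t> frontier, next;
  const int dk[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int di[6] = {0, 0, 0, 0, 1, -1};
  // initial border
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        R_xlen_t o = off3(k, j, i, nz, ny);
        int lab = labels[o];
        if (lab == 0) continue;
        bool border = false;
        for (int d = 0; d < 6 && !border; ++d) {
          int kk = k + dk[d], jj = j + dj[d], ii = i + di[d];
          if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
            border = true;
          else if (labels[off3(kk, jj, ii, nz, ny)] != lab)
            border = true;
        }
        if (border) { depth[o] = 0; frontier.push_back(o); }
      }
  int d = 0;
  R_xlen_t remaining = 0;
  for (R_xlen_t o = 0; o < n; ++o)
    if (labels[o] != 0 && depth[o] == -1) remaining++;
  while (!frontier.empty() && remaining > 0) {
    if (d >= cap) break;
    next.clear();
    for (R_xlen_t o : frontier) {
      int i = (int)(o / ((R_xlen_t)nz * ny));
      int j = (int)((o / nz) % ny);
      int k = (int)(o % nz);
      int lab = labels[o];
      for (int t = 0; t < 6; ++t) {
        int kk = k + dk[t], jj = j + dj[t], ii = i + di[t];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
          continue;
        R_xlen_t o2 = off3(kk, jj, ii, nz, ny);
        if (labels[o2] == lab && depth[o2] == -1) {
          depth[o2] = d + 1;
          next.push_back(o2);
          remaining--;
        }
      }
    }
    frontier.swap(next);
    d++;
  }
  // saturate anything never peeled (deep interior beyond cap)
  for (R_xlen_t o = 0; o < n; ++o)
    if (labels[o] != 0 && depth[o] == -1) depth[o] = cap;
  return depth;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> dk, dj, di;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dk.push_back(a); dj.push_back(b); di.push_back(c);
      }
  int nlab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t o = 0; o < n; ++o) {
    if (!mask[o] || lab[o] != 0) continue;
    nlab++;
    lab[o] = nlab;
    stack.clear();
    stack.push_back(o);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur / ((R_xlen_t)nz * ny));
      int j = (int)((cur / nz) % ny);
      int k = (int)(cur % nz);
      for (size_t t = 0; t < dk.size(); ++t) {
        int kk = k + dk[t], jj = j + dj[t], ii = i + di[t];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
          continue;
        R_xlen_t o2 = off3(kk, jj, ii, nz, ny);
        if (mask[o2] && lab[o2] == 0) { lab[o2] = nlab; stack.push_back(o2); }
      }
    }
  }
  return lab;
}

struct WsNode {
  double prio;       // dt value (flood from high to low)
  long long order;   // insertion counter, breaks ties deterministically
  R_xlen_t off;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on dt
    return a.order > b.order;                      // FIFO on ties
  }
};

// Marker-based watershed on -dt restricted to {dt >= floor}; 6-connected.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector dt, IntegerVector markers,
                            IntegerVector dims, double floorval) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  for (R_xlen_t o = 0; o < n; ++o)
    if (markers[o] != 0) {
      lab[o] = markers[o];
      pq.push({dt[o], counter++, o, markers[o]});
    }
  const int dk[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int di[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int i = (int)(nd.off / ((R_xlen_t)nz * ny));
    int j = (int)((nd.off / nz) % ny);
    int k = (int)(nd.off % nz);
    for (int t = 0; t < 6; ++t) {
      int kk = k + dk[t], jj = j + dj[t], ii = i + di[t];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
        continue;
      R_xlen_t o2 = off3(kk, jj, ii, nz, ny);
      if (lab[o2] == 0 && dt[o2] >= floorval) {
        lab[o2] = nd.label;
        pq.push({dt[o2], counter++, o2, nd.label});
      }
    }
  }
  return lab;
}

// Trilinear interpolation at physical (x, y, z) points, clamped to the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector data, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix points) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double oz = origin[0], oy = origin[1], ox = origin[2];
  int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double u = (points(p, 0) - ox) / sx;  // x index, 0-based continuous
    double v = (points(p, 1) - oy) / sy;
    double w = (points(p, 2) - oz) / sz;
    u = std::min(std::max(u, 0.0), (double)(nx - 1));
    v = std::min(std::max(v, 0.0), (double)(ny - 1));
    w = std::min(std::max(w, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(u), nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)std::floor(v), ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)std::floor(w), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fu = u - i0, fv = v - j0, fw = w - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = data[off3(k0, j0, i0, nz, ny)];
    double c001 = data[off3(k0, j0, i1, nz, ny)];
    double c010 = data[off3(k0, j1, i0, nz, ny)];
    double c011 = data[off3(k0, j1, i1, nz, ny)];
    double c100 = data[off3(k1, j0, i0, nz, ny)];
    double c101 = data[off3(k1, j0, i1, nz, ny)];
    double c110 = data[off3(k1, j1, i0, nz, ny)];
    double c111 = data[off3(k1, j1, i1, nz, ny)];
    double c00 = c000 * (1 - fu) + c001 * fu;
    double c01 = c010 * (1 - fu) + c011 * fu;
    double c10 = c100 * (1 - fu) + c101 * fu;
    double c11 = c110 * (1 - fu) + c111 * fu;
    double c0 = c00 * (1 - fv) + c01 * fv;
    double c1 = c10 * (1 - fv) + c11 * fv;
    out[p] = c0 * (1 - fw) + c1 * fw;
  }
  return out;
}

static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double& kv : ker) kv /= s;
  int dims[3] = {nz, ny, nx};
  int nax = dims[axis];
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        int idx[3] = {k, j, i};
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int q = idx[axis] + t;
          if (q < 0) q = 0;
          if (q >= nax) q = nax - 1;  // clamp padding
          int id2[3] = {idx[0], idx[1], idx[2]};
          id2[axis] = q;
          acc += ker[t + r] * src[off3(id2[0], id2[1], id2[2], nz, ny)];
        }
        dst[off3(k, j, i, nz, ny)] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector data, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(data.begin(), data.end()), b(n);
  blur_axis(a, b, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(b, a, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(a, b, nz, ny, nx, 2, sigma_vox[2]);
  return NumericVector(b.begin(), b.end());
}

// Ray march from `start` (physical xyz) along unit directions; returns, per
// ray, the last sample position that lies inside the region (nearest-voxel
// membership), marching to `tmax` with step `step`.
// [[Rcpp::export]]
NumericMatrix cpp_region_raymarch(LogicalVector region, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector start, NumericMatrix dirs,
                                  double step, double tmax) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double oz = origin[0], oy = origin[1], ox = origin[2];
  int nd = dirs.nrow();
  NumericMatrix out(nd, 3);
  for (int d = 0; d < nd; ++d) {
    double bx = start[0], by = start[1], bz = start[2];
    double lx = bx, ly = by, lz = bz;
    for (double t = 0; t <= tmax; t += step) {
      double px = bx + t * dirs(d, 0);
      double py = by + t * dirs(d, 1);
      double pz = bz + t * dirs(d, 2);
      int i = (int)std::lround((px - ox) / sx);
      int j = (int)std::lround((py - oy) / sy);
      int k = (int)std::lround((pz - oz) / sz);
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
      if (region[off3(k, j, i, nz, ny)]) { lx = px; ly = py; lz = pz; }
    }
    out(d, 0) = lx; out(d, 1) = ly; out(d, 2) = lz;
  }
  return out;
}
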