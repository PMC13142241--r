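#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Volumes are numeric/logical vectors with dim = c(nz, ny, nx), R column-major:
// linear index (0-based) = z + nz * (y + ny * x). Physical coordinate of voxel
// (z, y, x) is (z * sz, y * sy, x * sx) -- 0-based voxel-center convention.

static const double BIG = 1e20;

inline int64_t lin_idx(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * (int64_t)x);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas) with grid
// spacing s; f holds squared distances, d receives the transformed line.
static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double fq = f[q] + s2 * (double)q * (double)q;
    double s;
    while (true) {
      double fp = f[v[k]] + s2 * (double)v[k] * (double)v[k];
      s = (fq - fp) / (2.0 * s2 * (double)(q - v[k]));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform: distance (in physical units)
// from every voxel to the nearest foreground voxel of `mask`.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  NumericVector out(n);
  for (int64_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int maxlen = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxlen), d(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);

  // pass along each axis: axis 0 = z (stride 1), 1 = y (stride nz), 2 = x
  for (int axis = 0; axis < 3; axis++) {
    int len, n1, n2;
    int64_t stride, s1, s2v;
    if (axis == 0) { len = nz; stride = 1; n1 = ny; s1 = nz; n2 = nx; s2v = (int64_t)nz * ny; }
    else if (axis == 1) { len = ny; stride = nz; n1 = nz; s1 = 1; n2 = nx; s2v = (int64_t)nz * ny; }
    else { len = nx; stride = (int64_t)nz * ny; n1 = nz; s1 = 1; n2 = ny; s2v = nz; }
    if (len == 1) continue;
    double sp2 = spacing[axis] * spacing[axis];
    for (int a = 0; a < n1; a++) {
      for (int b = 0; b < n2; b++) {
        int64_t base = (int64_t)a * s1 + (int64_t)b * s2v;
        for (int q = 0; q < len; q++) f[q] = out[base + (int64_t)q * stride];
        dt1d(f.data(), d.data(), len, sp2, v, z);
        for (int q = 0; q < len; q++) out[base + (int64_t)q * stride] = d[q];
      }
    }
  }
  for (int64_t i = 0; i < n; i++) out[i] = out[i] >= BIG ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflecting boundary; sigma given per axis in
// voxels, a non-positive sigma skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, IntegerVector dim, NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(x);
  std::vector<double> buf;

  for (int axis = 0; axis < 3; axis++) {
    double sg = sigma[axis];
    if (sg <= 0) continue;
    int len, n1, n2;
    int64_t stride, s1, s2v;
    if (axis == 0) { len = nz; stride = 1; n1 = ny; s1 = nz; n2 = nx; s2v = (int64_t)nz * ny; }
    else if (axis == 1) { len = ny; stride = nz; n1 = nz; s1 = 1; n2 = nx; s2v = (int64_t)nz * ny; }
    else { len = nx; stride = (int64_t)nz * ny; n1 = nz; s1 = 1; n2 = ny; s2v = nz; }
    if (len == 1) continue;
    int r = (int)std::ceil(3.5 * sg);
    if (r < 1) r = 1;
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; k++) { w[k + r] = std::exp(-0.5 * k * k / (sg * sg)); tot += w[k + r]; }
    for (int k = 0; k <= 2 * r; k++) w[k] /= tot;
    buf.resize(len);
    for (int a = 0; a < n1; a++) {
      for (int b = 0; b < n2; b++) {
        int64_t base = (int64_t)a * s1 + (int64_t)b * s2v;
        for (int q = 0; q < len; q++) buf[q] = out[base + (int64_t)q * stride];
        for (int q = 0; q < len; q++) {
          double acc = 0.0;
          for (int k = -r; k <= r; k++) {
            int j = q + k;
            while (j < 0 || j >= len) {  // reflect about voxel edges
              if (j < 0) j = -j - 1;
              if (j >= len) j = 2 * len - j - 1;
            }
            acc += w[k + r] * buf[j];
          }
          out[base + (int64_t)q * stride] = acc;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a binary volume.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int64_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int64_t rest = cur / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (int dz = -1; dz <= 1; dz++) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; dx++) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int64_t j = lin_idx(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Fill interior cavities: background is flood-filled (6-connectivity) from
// the volume *edges* (voxels on at least two boundary faces); unreached
// background voxels become foreground. Edge seeding means the open lumen of
// a tube truncated by a volume face still counts as a cavity and is filled.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<int64_t> stack;
  for (int x = 0; x < nx; x++) {
    for (int y = 0; y < ny; y++) {
      for (int z = 0; z < nz; z++) {
        int nb = (z == 0 || z == nz - 1) + (y == 0 || y == ny - 1) +
                 (x == 0 || x == nx - 1);
        if (nb < 2) continue;
        int64_t i = lin_idx(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
    }
  }
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int64_t cur = stack.back();
    stack.pop_back();
    int z = (int)(cur % nz);
    int64_t rest = cur / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    for (int k = 0; k < 6; k++) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int64_t j = lin_idx(zz, yy, xx, nz, ny);
      if (!mask[j] && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (int64_t i = 0; i < n; i++) out[i] = mask[i] || !outside[i];
  return out;
}

// ---------------------------------------------------------------------------
// Grey-scale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary structuring element given as voxel offsets (rows of z, y, x);
// boundary handling is edge replication.
// [[Rcpp::export]]
NumericVector cpp_morph(NumericVector x, IntegerVector dim, IntegerMatrix offsets, bool dilate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  int m = offsets.nrow();
  NumericVector out(n);
  for (int xx = 0; xx < nx; xx++) {
    for (int yy = 0; yy < ny; yy++) {
      for (int zz = 0; zz < nz; zz++) {
        double best = dilate ? -BIG : BIG;
        for (int k = 0; k < m; k++) {
          int z2 = zz + offsets(k, 0);
          int y2 = yy + offsets(k, 1);
          int x2 = xx + offsets(k, 2);
          if (z2 < 0) z2 = 0; else if (z2 >= nz) z2 = nz - 1;
          if (y2 < 0) y2 = 0; else if (y2 >= ny) y2 = ny - 1;
          if (x2 < 0) x2 = 0; else if (x2 >= nx) x2 = nx - 1;
          double v = x[lin_idx(z2, y2, x2, nz, ny)];
          if (dilate) { if (v > best) best = v; } else { if (v < best) best = v; }
        }
        out[lin_idx(zz, yy, xx, nz, ny)] = best;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local maxima over the 26-neighbourhood (>= all neighbours, value > floor);
// returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_max26(NumericVector x, IntegerVector dim, double floor_val) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int64_t> hits;
  for (int xx = 0; xx < nx; xx++) {
    for (int yy = 0; yy < ny; yy++) {
      for (int zz = 0; zz < nz; zz++) {
        int64_t i = lin_idx(zz, yy, xx, nz, ny);
        double v = x[i];
        if (!(v > floor_val)) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; dz++) {
          int z2 = zz + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -1; dy <= 1 && is_max; dy++) {
            int y2 = yy + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -1; dx <= 1; dx++) {
              int x2 = xx + dx;
              if (x2 < 0 || x2 >= nx) continue;
              if (dz == 0 && dy == 0 && dx == 0) continue;
              if (x[lin_idx(z2, y2, x2, nz, ny)] > v) { is_max = false; break; }
            }
          }
        }
        if (is_max) hits.push_back(i + 1);
      }
    }
  }
  IntegerVector out(hits.size());
  for (size_t k = 0; k < hits.size(); k++) out[k] = (int)hits[k];
  return out;
}

// ---------------------------------------------------------------------------
// Union of solid ellipsoids with continuous centers (micrometers, z/y/x
// columns) and common per-axis semi-axes; returns a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_sphere_union(IntegerVector dim, NumericVector spacing,
                               NumericMatrix centers_um, NumericVector radii_um) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  LogicalVector out(n, false);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double rz = radii_um[0], ry = radii_um[1], rx = radii_um[2];
  for (int c = 0; c < centers_um.nrow(); c++) {
    double cz = centers_um(c, 0), cy = centers_um(c, 1), cx = centers_um(c, 2);
    int z0 = std::max(0, (int)std::ceil((cz - rz) / sz));
    int z1 = std::min(nz - 1, (int)std::floor((cz + rz) / sz));
    int y0 = std::max(0, (int)std::ceil((cy - ry) / sy));
    int y1 = std::min(ny - 1, (int)std::floor((cy + ry) / sy));
    int x0 = std::max(0, (int)std::ceil((cx - rx) / sx));
    int x1 = std::min(nx - 1, (int)std::floor((cx + rx) / sx));
    for (int xx = x0; xx <= x1; xx++) {
      double dx = (xx * sx - cx) / rx;
      for (int yy = y0; yy <= y1; yy++) {
        double dy = (yy * sy - cy) / ry;
        double dxy2 = dx * dx + dy * dy;
        if (dxy2 > 1.0) continue;
        for (int zz = z0; zz <= z1; zz++) {
          double dz = (zz * sz - cz) / rz;
          if (dz * dz + dxy2 <= 1.0) out[lin_idx(zz, yy, xx, nz, ny)] = true;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Grey erosion/dilation with an ellipsoidal structuring element of a common
// physical radius, anisotropy-corrected per axis. The ellipsoid is swept as
// one sliding min/max window along x per (dz, dy) offset pair (monotonic
// deque, O(1) amortized per voxel), with edge replication.
static void sliding_extreme(const double* in, double* out, int n, int halfwin,
                            bool maxmode, std::vector<int>& dq) {
  dq.clear();
  int head = 0;  // emulate deque with vector + head index
  for (int i = 0; i < n + halfwin; i++) {
    if (i < n) {
      while ((int)dq.size() > head &&
             (maxmode ? in[dq.back()] <= in[i] : in[dq.back()] >= in[i])) {
        dq.pop_back();
      }
      dq.push_back(i);
    }
    int pos = i - halfwin;  // output position whose window [pos-h, pos+h] is complete
    if (pos >= 0) {
      while (dq[head] < pos - halfwin) head++;
      out[pos] = in[dq[head]];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_morph_ellipsoid(NumericVector x, IntegerVector dim,
                                  NumericVector spacing, double radius_um,
                                  bool dilate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int64_t n = (int64_t)nz * ny * nx;
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  int rz = (int)std::floor(radius_um / sz);
  int ry = (int)std::floor(radius_um / sy);

  // offset pairs (dz, dy) inside the ellipsoid with their x half-window
  std::vector<int> pdz, pdy, plx;
  for (int dz = -rz; dz <= rz; dz++) {
    for (int dy = -ry; dy <= ry; dy++) {
      double rem = radius_um * radius_um - dz * sz * dz * sz - dy * sy * dy * sy;
      if (rem < 0) continue;
      pdz.push_back(dz);
      pdy.push_back(dy);
      plx.push_back((int)std::floor(std::sqrt(rem) / sx));
    }
  }

  // work in an x-fastest transposed copy so every line pass is contiguous
  std::vector<double> src(n), dst(n, dilate ? -BIG : BIG);
  const double* xin = REAL(x);
  for (int xx = 0; xx < nx; xx++) {
    for (int y = 0; y < ny; y++) {
      const double* col = xin + (int64_t)nz * (y + (int64_t)ny * xx);
      for (int z = 0; z < nz; z++) {
        src[(int64_t)xx + (int64_t)nx * (y + (int64_t)ny * z)] = col[z];
      }
    }
  }

  std::vector<double> extr(nx);
  std::vector<int> dq;
  dq.reserve(nx + 1);
  for (size_t p = 0; p < pdz.size(); p++) {
    int dz = pdz[p], dy = pdy[p], lx = plx[p];
    for (int z = 0; z < nz; z++) {
      int zs = z + dz;
      if (zs < 0) zs = 0; else if (zs >= nz) zs = nz - 1;
      for (int y = 0; y < ny; y++) {
        int ys = y + dy;
        if (ys < 0) ys = 0; else if (ys >= ny) ys = ny - 1;
        const double* line = src.data() + (int64_t)nx * (ys + (int64_t)ny * zs);
        double* outline = dst.data() + (int64_t)nx * (y + (int64_t)ny * z);
        sliding_extreme(line, extr.data(), nx, lx, dilate, dq);
        if (dilate) {
          for (int xx = 0; xx < nx; xx++) {
            if (extr[xx] > outline[xx]) outline[xx] = extr[xx];
          }
        } else {
          for (int xx = 0; xx < nx; xx++) {
            if (extr[xx] < outline[xx]) outline[xx] = extr[xx];
          }
        }
      }
    }
  }

  NumericVector out(n);
  double* oput = REAL(out);
  for (int xx = 0; xx < nx; xx++) {
    for (int y = 0; y < ny; y++) {
      double* col = oput + (int64_t)nz * (y + (int64_t)ny * xx);
      for (int z = 0; z < nz; z++) {
        col[z] = dst[(int64_t)xx + (int64_t)nx * (y + (int64_t)ny * z)];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Solid tube swept along a polyline (points in micrometers, z/y/x columns):
// voxels whose center lies within radius_um of any segment are set.
// [[Rcpp::export]]
LogicalVector cpp_tube_mask(IntegerVector dim, NumericVector spacing,
                            NumericMatrix points_um, double radius_um,
                            LogicalVector carry) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out = clone(carry);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double r2 = radius_um * radius_um;
  int np = points_um.nrow();
  for (int s = 0; s < np - 1; s++) {
    double az = points_um(s, 0), ay = points_um(s, 1), ax = points_um(s, 2);
    double bz = points_um(s + 1, 0), by = points_um(s + 1, 1), bx = points_um(s + 1, 2);
    double lo_z = std::min(az, bz) - radius_um, hi_z = std::max(az, bz) + radius_um;
    double lo_y = std::min(ay, by) - radius_um, hi_y = std::max(ay, by) + radius_um;
    double lo_x = std::min(ax, bx) - radius_um, hi_x = std::max(ax, bx) + radius_um;
    int z0 = std::max(0, (int)std::ceil(lo_z / sz));
    int z1 = std::min(nz - 1, (int)std::floor(hi_z / sz));
    int y0 = std::max(0, (int)std::ceil(lo_y / sy));
    int y1 = std::min(ny - 1, (int)std::floor(hi_y / sy));
    int x0 = std::max(0, (int)std::ceil(lo_x / sx));
    int x1 = std::min(nx - 1, (int)std::floor(hi_x / sx));
    double vz = bz - az, vy = by - ay, vx = bx - ax;
    double vv = vz * vz + vy * vy + vx * vx;
    for (int xx = x0; xx <= x1; xx++) {
      double px = xx * sx;
      for (int yy = y0; yy <= y1; yy++) {
        double py = yy * sy;
        for (int zz = z0; zz <= z1; zz++) {
          double pz = zz * sz;
          double wz = pz - az, wy = py - ay, wx = px - ax;
          double t = vv > 0 ? (wz * vz + wy * vy + wx * vx) / vv : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dz = wz - t * vz, dy = wy - t * vy, dx = wx - t * vx;
          if (dz * dz + dy * dy + dx * dx <= r2) {
            out[lin_idx(zz, yy, xx, nz, ny)] = true;
          }
        }
      }
    }
  }
  return out;
}
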