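#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <queue>
#include <vector>
using namespace Rcpp;

// Voxel-grid primitives shared by the layering and segmentation stages.
// All arrays are column-major (R layout), dims = (nx, ny, nz), 0-based here.

static const double BIG = 1e20;

// 1-D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher)
// on samples at physical positions i*h, i = 0..n-1.
static inline double isect(const std::vector<double>& f, int q, int p,
                           double h) {
  double qh = q * h, ph = p * h;
  return ((f[q] + qh * qh) - (f[p] + ph * ph)) / (2.0 * qh - 2.0 * ph);
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;  // f is capped at BIG (finite), so intersections stay finite
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = isect(f, q, v[k], h);
    while (s <= z[k]) {
      --k;
      s = isect(f, q, v[k], h);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qh = q * h;
    while (z[k + 1] < qh) ++k;
    double vh = v[k] * h;
    d[q] = (qh - vh) * (qh - vh) + f[v[k]];
  }
}

// Exact Euclidean distance transform in mm: distance from every voxel center
// to the nearest TRUE voxel center of `mask`, with anisotropic spacing.
// Voxels with no TRUE voxel anywhere get Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int xx = 0; xx < nx; ++xx) f[xx] = out[base + xx];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int xx = 0; xx < nx; ++xx) out[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; ++yy) f[yy] = out[base + (R_xlen_t)yy * nx];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int yy = 0; yy < ny; ++yy) out[base + (R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + (R_xlen_t)zz * nxy];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int zz = 0; zz < nz; ++zz) out[base + (R_xlen_t)zz * nxy] = d[zz];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= BIG / 2) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// 6-connected component labelling; labels 1..k in first-encounter order,
// background 0.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front();
      q.pop();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), zz = (int)(i / nxy);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int X = x + dx[k], Y = y + dy[k], Z = zz + dz[k];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t j = (R_xlen_t)Z * nxy + (R_xlen_t)Y * nx + X;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Connected-threshold region growing: 6-connected flood from `seed` (0-based
// linear index) over voxels with allowed && lo <= img <= hi.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, LogicalVector allowed,
                              IntegerVector dim, double seed_idx, double lo,
                              double hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  LogicalVector out(n, false);
  R_xlen_t s = (R_xlen_t)seed_idx;
  if (s < 0 || s >= n) stop("seed index out of range");
  if (!(allowed[s] && img[s] >= lo && img[s] <= hi)) return out;
  std::queue<R_xlen_t> q;
  out[s] = true;
  q.push(s);
  while (!q.empty()) {
    R_xlen_t i = q.front();
    q.pop();
    int x = (int)(i % nx), y = (int)((i / nx) % ny), zz = (int)(i / nxy);
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int X = x + dx[k], Y = y + dy[k], Z = zz + dz[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      R_xlen_t j = (R_xlen_t)Z * nxy + (R_xlen_t)Y * nx + X;
      if (!out[j] && allowed[j] && img[j] >= lo && img[j] <= hi) {
        out[j] = true;
        q.push(j);
      }
    }
  }
  return out;
}

// Anti-aliased interface distance: given a smoothed occupancy indicator in
// [0, 1], the boundary is where the indicator crosses 0.5. Crossings are
// located to sub-voxel precision by linear interpolation along each grid
// axis; parabolas rooted at those off-lattice positions seed a separable
// squared-distance transform (one family per axis, minimum over families).
// Both sides of the boundary get positive distances. Inf if the indicator
// never crosses 0.5.
// [[Rcpp::export]]
NumericVector cpp_interface_dist(NumericVector ind, IntegerVector dim,
                                 NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), sq(nmax), f(nmax), d(nmax), z(nmax + 1);
  std::vector<double> cross;
  std::vector<int> v(nmax);
  std::vector<double> fam(n);
  NumericVector best(n, BIG);

  int nn[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, nxy};

  for (int axis = 0; axis < 3; ++axis) {
    int na = nn[axis];
    double h = spacing[axis];
    int b1 = (axis + 1) % 3, b2 = (axis + 2) % 3;
    bool any_cross = false;
    // pass 1: squared distance to level crossings along this axis
    for (int j2 = 0; j2 < nn[b2]; ++j2)
      for (int j1 = 0; j1 < nn[b1]; ++j1) {
        R_xlen_t base = (R_xlen_t)j2 * stride[b2] + (R_xlen_t)j1 * stride[b1];
        for (int q = 0; q < na; ++q)
          line[q] = ind[base + (R_xlen_t)q * stride[axis]];
        cross.clear();
        for (int q = 0; q + 1 < na; ++q) {
          double a = line[q] - 0.5, b = line[q + 1] - 0.5;
          if (a == 0.0) cross.push_back(q * h);
          if ((a < 0 && b > 0) || (a > 0 && b < 0))
            cross.push_back((q + a / (a - b)) * h);
        }
        if (line[na - 1] == 0.5) cross.push_back((na - 1) * h);
        if (cross.empty()) {
          for (int q = 0; q < na; ++q)
            sq[q] = BIG;
        } else {
          any_cross = true;
          size_t k = 0;
          for (int q = 0; q < na; ++q) {
            double qh = q * h;
            while (k + 1 < cross.size() &&
                   std::fabs(cross[k + 1] - qh) <= std::fabs(cross[k] - qh))
              ++k;
            double dd = qh - cross[k];
            sq[q] = dd * dd;
          }
        }
        for (int q = 0; q < na; ++q)
          fam[base + (R_xlen_t)q * stride[axis]] = sq[q];
      }
    if (!any_cross) continue;
    // passes 2 and 3: standard envelope transform along the other axes
    for (int pass = 0; pass < 2; ++pass) {
      int pa = pass == 0 ? b1 : b2;
      int oa = pass == 0 ? b2 : b1;
      int np = nn[pa];
      for (int jo = 0; jo < nn[oa]; ++jo)
        for (int ja = 0; ja < na; ++ja) {
          R_xlen_t base = (R_xlen_t)jo * stride[oa] +
            (R_xlen_t)ja * stride[axis];
          for (int q = 0; q < np; ++q)
            f[q] = fam[base + (R_xlen_t)q * stride[pa]];
          dt1d(f, d, np, spacing[pa], v, z);
          for (int q = 0; q < np; ++q)
            fam[base + (R_xlen_t)q * stride[pa]] = d[q];
        }
    }
    for (R_xlen_t i = 0; i < n; ++i)
      if (fam[i] < best[i]) best[i] = fam[i];
  }
  for (R_xlen_t i = 0; i < n; ++i)
    best[i] = (best[i] >= BIG / 2) ? R_PosInf : std::sqrt(best[i]);
  return best;
}

// Largest pairwise Euclidean distance between rows of a point matrix (mm).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  R_xlen_t n = pts.nrow();
  double best = 0.0;
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
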