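#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Squared Euclidean distance transform of a 3D binary field, separable
// lower-envelope algorithm (Felzenszwalb & Huttenlocher), generalized to
// anisotropic sample spacing.  Distances are voxel-center to voxel-center
// in physical units.  Input f holds 0 at feature (background) voxels and
// +inf elsewhere; output holds squared distance to the nearest feature
// voxel center.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) {
      // both parabolas at infinity: keep the earlier one
      continue;
    }
    double sden = 2.0 * s2 * (q - v[k]);
    double snum = (f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k]);
    double sx = snum / sden;
    while (k > 0 && sx <= z[k]) {
      --k;
      sden = 2.0 * s2 * (q - v[k]);
      snum = (f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k]);
      sx = snum / sden;
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector feature, IntegerVector dim,
                     NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = feature[i] ? 0.0 : INF;

  // R arrays are column-major: index = z + nz*(y + ny*x)
  std::vector<double> f, d;

  // pass along z (stride 1)
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = out[base + z];
      dt1d(f, d, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }

  // pass along y (stride nz)
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nz * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nz * y] = d[y];
    }

  // pass along x (stride nz*ny)
  f.resize(nx); d.resize(nx);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = out[base + sx * x];
      dt1d(f, d, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) out[base + sx * x] = d[x];
    }

  return out;
}
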