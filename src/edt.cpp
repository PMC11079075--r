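#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher). Sample positions are q * s where s is the
// voxel spacing along the line; s2 = s^2 is folded into the parabola
// arithmetic. Handles infinite inputs (empty lines stay infinite).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == DINF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
          (2.0 * s2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = DINF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = DINF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    d[q] = f[p] + s2 * (double)(q - p) * (q - p);
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D grid.
// init: column-major array, 0 at source voxels, +Inf elsewhere.
// Returns squared distance (mm^2) to the nearest source voxel centre.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(NumericVector init, IntegerVector dims,
                         NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3)
    stop("dims and spacing must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != init.size())
    stop("init length does not match dims");
  NumericVector out = clone(init);

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // axis 0 (stride 1)
  {
    const double s2 = spacing[0] * spacing[0];
    for (int kz = 0; kz < nz; ++kz)
      for (int jy = 0; jy < ny; ++jy) {
        R_xlen_t base = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
        for (int i = 0; i < nx; ++i) f[i] = out[base + i];
        dt1d(f, d, nx, s2);
        for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      }
  }
  // axis 1 (stride nx)
  {
    const double s2 = spacing[1] * spacing[1];
    for (int kz = 0; kz < nz; ++kz)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t base = ix + (R_xlen_t)nx * ny * kz;
        for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
        dt1d(f, d, ny, s2);
        for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
      }
  }
  // axis 2 (stride nx*ny)
  {
    const double s2 = spacing[2] * spacing[2];
    const R_xlen_t st = (R_xlen_t)nx * ny;
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t base = ix + (R_xlen_t)nx * jy;
        for (int k = 0; k < nz; ++k) f[k] = out[base + st * k];
        dt1d(f, d, nz, s2);
        for (int k = 0; k < nz; ++k) out[base + st * k] = d[k];
      }
  }
  return out;
}
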