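#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower envelope of parabolas). f and d of length n; v, z are
// scratch buffers of length n and n + 1.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
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
    int p = v[k];
    d[q] = (q - p) * (double)(q - p) + f[p];
  }
}

// Exact squared Euclidean distance (voxel units, centre-to-centre) from every
// voxel to the nearest voxel where mask is FALSE. Voxels of an all-TRUE mask
// get Inf.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite initial value: true infinity would produce -inf parabola
  // intersections and pop the -inf sentinel of the lower envelope
  const double INF = 1e15;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = &out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx];
      dt1d(row, f.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) row[i] = f[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j)
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k)
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = d[k];
    }
  return out;
}
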