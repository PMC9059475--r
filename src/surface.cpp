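#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kuhn 6-tetrahedra decomposition of the unit cube; cube corner l has offsets
// (l & 1, (l >> 1) & 1, (l >> 2) & 1). All tets share the 0-7 diagonal, so
// shared faces between neighbouring cells are triangulated consistently.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  const double u0 = b[0] - a[0], u1 = b[1] - a[1], u2 = b[2] - a[2];
  const double v0 = c[0] - a[0], v1 = c[1] - a[1], v2 = c[2] - a[2];
  const double cx = u1 * v2 - u2 * v1;
  const double cy = u2 * v0 - u0 * v2;
  const double cz = u0 * v1 - u1 * v0;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void interp(const double* p, const double* q, double fp,
                          double fq, double iso, double out[3]) {
  const double t = (iso - fp) / (fq - fp);
  for (int d = 0; d < 3; ++d) out[d] = p[d] + t * (q[d] - p[d]);
}

// Total area of the triangulated isosurface of a scalar field sampled at voxel
// centres, by marching tetrahedra. No padding is applied, so surface pieces
// that would close against the array boundary are not generated (open VOI
// faces). Area is in voxel units squared.
// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  double total = 0.0;
  double corner[8][3], fval[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int npos = 0;
        for (int l = 0; l < 8; ++l) {
          const int di = l & 1, dj = (l >> 1) & 1, dk = (l >> 2) & 1;
          double f = field[(R_xlen_t)(k + dk) * nxy +
                           (R_xlen_t)(j + dj) * nx + (i + di)];
          if (f == iso) f = iso + 1e-12 * (std::fabs(iso) + 1.0);
          fval[l] = f;
          corner[l][0] = i + di; corner[l][1] = j + dj; corner[l][2] = k + dk;
          if (f > iso) ++npos;
        }
        if (npos == 0 || npos == 8) continue;

        for (int t = 0; t < 6; ++t) {
          const int* v = TETS[t];
          int pos[4], neg[4], np = 0, nn = 0;
          for (int m = 0; m < 4; ++m) {
            if (fval[v[m]] > iso) pos[np++] = v[m]; else neg[nn++] = v[m];
          }
          if (np == 0 || np == 4) continue;
          double e[4][3];
          if (np == 1 || np == 3) {
            const int apex = (np == 1) ? pos[0] : neg[0];
            const int* base = (np == 1) ? neg : pos;
            for (int m = 0; m < 3; ++m)
              interp(corner[apex], corner[base[m]], fval[apex], fval[base[m]],
                     iso, e[m]);
            total += tri_area(e[0], e[1], e[2]);
          } else {  // 2-2: quad across edges a-c, a-d, b-d, b-c
            const int a = pos[0], b = pos[1], c = neg[0], d = neg[1];
            interp(corner[a], corner[c], fval[a], fval[c], iso, e[0]);
            interp(corner[a], corner[d], fval[a], fval[d], iso, e[1]);
            interp(corner[b], corner[d], fval[b], fval[d], iso, e[2]);
            interp(corner[b], corner[c], fval[b], fval[c], iso, e[3]);
            total += tri_area(e[0], e[1], e[2]) + tri_area(e[0], e[2], e[3]);
          }
        }
      }
  return total;
}

// Separable Gaussian smoothing with edge replication; sigma in voxels.
// [[Rcpp::export(name = ".gauss_smooth3")]]
NumericVector gauss_smooth3(NumericVector field, IntegerVector dim,
                            double sigma, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<double> w(2 * radius + 1);
  double wsum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    w[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    wsum += w[t + radius];
  }
  for (double& v : w) v /= wsum;

  NumericVector a = clone(field), b(a.size());
  const int strides[3] = {1, nx, (int)nxy};
  const int lens[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const R_xlen_t stride = strides[axis];
    const int len = lens[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int pos = (axis == 0) ? i : (axis == 1 ? j : k);
          const R_xlen_t idx = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
          double acc = 0.0;
          for (int t = -radius; t <= radius; ++t) {
            int p = pos + t;
            if (p < 0) p = 0;
            if (p >= len) p = len - 1;
            acc += w[t + radius] * a[idx + (R_xlen_t)(p - pos) * stride];
          }
          b[idx] = acc;
        }
    std::swap(a, b);
  }
  return a;
}
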