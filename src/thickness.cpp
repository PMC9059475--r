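#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Hildebrand-Ruegsegger local thickness by maximal-sphere painting.
// dt: Euclidean distance (voxel units) from each foreground voxel to the
// nearest background voxel centre; 0 on background. Every foreground voxel is
// assigned 2 * R - 0.5 voxels, where R is the largest dt among sphere centres
// whose sphere (radius R - 0.5, i.e. offset to the continuous boundary)
// contains the voxel. Redundant centres (whose sphere lies inside a
// neighbour's sphere) are pruned before painting.
// [[Rcpp::export(name = ".local_thickness_vox")]]
NumericVector local_thickness_vox(NumericVector dt, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  NumericVector out(n);

  struct Center { double r; int i, j, k; };
  std::vector<Center> centers;
  centers.reserve(1024);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double r = dt[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i];
        if (r <= 0) continue;
        // prune c if a 26-neighbour n has dt(n) >= dt(c) + |n - c|
        bool redundant = false;
        for (int dk = -1; dk <= 1 && !redundant; ++dk)
          for (int dj = -1; dj <= 1 && !redundant; ++dj)
            for (int di = -1; di <= 1 && !redundant; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              const double rn = dt[(R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii];
              const double sep = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (rn >= r + sep) redundant = true;
            }
        if (!redundant) centers.push_back({r, i, j, k});
      }

  std::sort(centers.begin(), centers.end(),
            [](const Center& a, const Center& b) { return a.r > b.r; });

  for (const Center& c : centers) {
    // inscribed-sphere radius is r - 0.5 (centre-to-boundary); a voxel is
    // covered when its centre is within half a voxel of the sphere
    const double rad = c.r;
    const double val = 2.0 * c.r - 0.5;
    const int w = (int)std::floor(std::max(rad, 0.0));
    const double rad2 = rad * rad;
    for (int dk = -w; dk <= w; ++dk) {
      const int kk = c.k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -w; dj <= w; ++dj) {
        const int jj = c.j + dj;
        if (jj < 0 || jj >= ny) continue;
        const double d2 = (double)dk * dk + (double)dj * dj;
        if (d2 > rad2) continue;
        const int wi = (int)std::floor(std::sqrt(rad2 - d2));
        const R_xlen_t base = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx;
        const int lo = std::max(c.i - wi, 0), hi = std::min(c.i + wi, nx - 1);
        for (int ii = lo; ii <= hi; ++ii)
          if (out[base + ii] < val && dt[base + ii] > 0) out[base + ii] = val;
      }
    }
    // the centre itself (w may be 0 yet rad < 1)
    const R_xlen_t ci = (R_xlen_t)c.k * nxy + (R_xlen_t)c.j * nx + c.i;
    if (out[ci] < val) out[ci] = val;
  }
  return out;
}
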