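#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Assemble COO triplets (upper triangle, 1-based) for a voxel-hex mesh in
// which every element of material m shares the same 24 x 24 stiffness kmats[m].
// DOF numbering: dof = 3 * node + component.
// [[Rcpp::export(name = ".fe_triplets")]]
List fe_triplets(IntegerMatrix elem_nodes, IntegerVector mat, List kmats) {
  const int nel = elem_nodes.nrow();
  const int nmat = kmats.size();
  std::vector<NumericMatrix> ks;
  ks.reserve(nmat);
  for (int m = 0; m < nmat; ++m) ks.push_back(as<NumericMatrix>(kmats[m]));

  const R_xlen_t per = 24 * 25 / 2;
  IntegerVector I((R_xlen_t)nel * per), J((R_xlen_t)nel * per);
  NumericVector X((R_xlen_t)nel * per);

  R_xlen_t pos = 0;
  int dof[24];
  for (int e = 0; e < nel; ++e) {
    const NumericMatrix& ke = ks[mat[e]];
    for (int l = 0; l < 8; ++l) {
      const int node = elem_nodes(e, l);
      dof[3 * l] = 3 * node;
      dof[3 * l + 1] = 3 * node + 1;
      dof[3 * l + 2] = 3 * node + 2;
    }
    for (int a = 0; a < 24; ++a)
      for (int b = a; b < 24; ++b) {
        int gi = dof[a], gj = dof[b];
        double v = ke(a, b);
        if (gi > gj) { const int t = gi; gi = gj; gj = t; }
        I[pos] = gi + 1;
        J[pos] = gj + 1;
        X[pos] = v;
        ++pos;
      }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}

// Element-centre strains for trilinear voxel hexahedra of side h (the centre
// B-matrix equals the element-mean B, so this is consistent with B-bar
// integration). Returns nel x 6 engineering strains
// (exx, eyy, ezz, gxy, gyz, gzx).
// [[Rcpp::export(name = ".fe_strains")]]
NumericMatrix fe_strains(IntegerMatrix elem_nodes, NumericVector u, double h) {
  const int nel = elem_nodes.nrow();
  NumericMatrix eps(nel, 6);
  const double g = 1.0 / (4.0 * h);
  for (int e = 0; e < nel; ++e) {
    double exx = 0, eyy = 0, ezz = 0, gxy = 0, gyz = 0, gzx = 0;
    for (int l = 0; l < 8; ++l) {
      const int node = elem_nodes(e, l);
      const double sx = (l & 1) ? g : -g;
      const double sy = ((l >> 1) & 1) ? g : -g;
      const double sz = ((l >> 2) & 1) ? g : -g;
      const double ux = u[3 * node], uy = u[3 * node + 1], uz = u[3 * node + 2];
      exx += sx * ux;
      eyy += sy * uy;
      ezz += sz * uz;
      gxy += sy * ux + sx * uy;
      gyz += sz * uy + sy * uz;
      gzx += sx * uz + sz * ux;
    }
    eps(e, 0) = exx; eps(e, 1) = eyy; eps(e, 2) = ezz;
    eps(e, 3) = gxy; eps(e, 4) = gyz; eps(e, 5) = gzx;
  }
  return eps;
}
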