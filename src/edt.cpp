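#include <Rcpp.h>
#include "common.h"
using namespace Rcpp;

// Euclidean distance transform of a (nz, ny, nx) binary array: distance from
// every voxel to the nearest voxel where mask != 0, honouring anisotropic
// physical spacing (hz, hy, hx).  Voxels are Inf when the mask is empty.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a((size_t)nz * ny * nx);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    a[i] = (mask[i] != 0 && mask[i] != NA_INTEGER) ? 0.0 : DT_BIG;
  edt3d_sq(a, nz, ny, nx, spacing[0], spacing[1], spacing[2]);
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = a[i] > 1e19 ? R_PosInf : std::sqrt(a[i]);
  out.attr("dim") = dim;
  return out;
}
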