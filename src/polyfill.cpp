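#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Even-odd scanline rasterization of a closed polygon.  Vertex coordinates
// are in pixel units where integer values are pixel centers.  Returns a
// logical (ny x nx) matrix whose cell (i, j) is TRUE when the center of pixel
// (y0 + i - 1, x0 + j - 1) lies strictly inside the polygon.  Horizontal
// edges never generate crossings (half-open rule), and a center exactly on a
// crossing is counted outside, so counts are reproducible.
// [[Rcpp::export(name = ".poly_fill")]]
LogicalMatrix poly_fill(NumericVector vy, NumericVector vx,
                        int y0, int ny, int x0, int nx) {
  const int n = vy.size();
  if (n < 3) stop("polygon needs at least 3 vertices");
  LogicalMatrix out(ny, nx);
  std::vector<double> xs;
  for (int i = 0; i < ny; ++i) {
    const double cy = (double)(y0 + i);
    xs.clear();
    for (int e = 0; e < n; ++e) {
      const int e2 = (e + 1 == n) ? 0 : e + 1;
      const double y1 = vy[e], y2 = vy[e2];
      if ((y1 <= cy && y2 > cy) || (y2 <= cy && y1 > cy)) {
        const double t = (cy - y1) / (y2 - y1);
        xs.push_back(vx[e] + t * (vx[e2] - vx[e]));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      // strictly inside: centers with xs[k] < cx < xs[k+1]
      int jlo = (int)std::ceil(xs[k] - (double)x0 + 1e-12);
      int jhi = (int)std::floor(xs[k + 1] - (double)x0 - 1e-12);
      if (jlo < 0) jlo = 0;
      if (jhi > nx - 1) jhi = nx - 1;
      for (int j = jlo; j <= jhi; ++j) out(i, j) = TRUE;
    }
  }
  return out;
}
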