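#ifndef MITOSEG_COMMON_H
#define MITOSEG_COMMON_H

#include <vector>
#include <limits>
#include <cmath>

// Finite stand-in for +Inf: keeps the parabola intersections finite.  Callers
// mark non-feature cells with DT_BIG; any squared distance reachable on a
// real grid is far below it.
const double DT_BIG = 1e20;

// 1D squared-distance transform (lower envelope of parabolas), Felzenszwalb &
// Huttenlocher.  f holds squared distances on input, d the transformed values;
// h is the physical sample step along this axis.
inline void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double num = (f[q] + (double)q * q * h * h) - (f[v[k]] + (double)v[k] * v[k] * h * h);
      double den = 2.0 * h * (q - v[k]);   // intersection in physical coordinates
      s = num / den;
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q * h) ++k;
    double dq = ((double)q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// In-place 3D squared EDT on a (nz, ny, nx) column-major array (z fastest),
// anisotropic spacing (hz, hy, hx).  On input, cells must be 0 (feature) or
// +Inf (non-feature); on output, squared distance to nearest feature cell.
inline void edt3d_sq(std::vector<double>& a, int nz, int ny, int nx,
                     double hz, double hy, double hx) {
  std::vector<double> f, d;
  // along z (stride 1)
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const long base = (long)nz * (y + (long)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = a[base + z];
      dt1d(f, d, hz);
      for (int z = 0; z < nz; ++z) a[base + z] = d[z];
    }
  // along y (stride nz)
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      const long base = z + (long)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = a[base + (long)nz * y];
      dt1d(f, d, hy);
      for (int y = 0; y < ny; ++y) a[base + (long)nz * y] = d[y];
    }
  // along x (stride nz*ny)
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      const long base = z + (long)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = a[base + (long)nz * ny * x];
      dt1d(f, d, hx);
      for (int x = 0; x < nx; ++x) a[base + (long)nz * ny * x] = d[x];
    }
}

#endif
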