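#include <Rcpp.h>
#include "common.h"
using namespace Rcpp;

// Geodesic active contour evolution on a (nz, ny, nx) grid.
//
//   phi_t = -prop * g * |grad phi|_upwind
//           + curv * g * kappa * |grad phi|
//           + adv  * (grad g . grad phi)_upwind
//
// phi < 0 is the interior.  g in (0, 1] is the edge-potential speed (low on
// edges).  Work is restricted to a narrow band |phi| <= band; the time step
// is chosen each iteration from the CFL bound over the band, and phi is
// periodically reinitialized to a signed distance from its zero level so the
// band stays well conditioned.  spacing = (hz, hy, hx) in the same length
// unit as phi.

static inline long IDX(int z, int y, int x, int nz, int ny) {
  return (long)z + (long)nz * ((long)y + (long)ny * x);
}

// [[Rcpp::export(name = ".gac_evolve")]]
List gac_evolve(NumericVector phi_in, NumericVector g_in, NumericVector spacing,
                double prop, double curv, double adv,
                int max_iter, double rms_tol, double band, int reinit_every) {
  IntegerVector dim = phi_in.attr("dim");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long N = (long)nz * ny * nx;
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  std::vector<double> phi(phi_in.begin(), phi_in.end());
  const double* g = g_in.begin();

  // central gradient of g, precomputed once
  std::vector<double> gz(N), gy(N), gx(N);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const long i = IDX(z, y, x, nz, ny);
        const int zp = z + 1 < nz ? z + 1 : z, zm = z > 0 ? z - 1 : z;
        const int yp = y + 1 < ny ? y + 1 : y, ym = y > 0 ? y - 1 : y;
        const int xp = x + 1 < nx ? x + 1 : x, xm = x > 0 ? x - 1 : x;
        gz[i] = (g[IDX(zp, y, x, nz, ny)] - g[IDX(zm, y, x, nz, ny)]) / ((zp - zm) * hz);
        gy[i] = (g[IDX(z, yp, x, nz, ny)] - g[IDX(z, ym, x, nz, ny)]) / ((yp - ym) * hy);
        gx[i] = (g[IDX(z, y, xp, nz, ny)] - g[IDX(z, y, xm, nz, ny)]) / ((xp - xm) * hx);
      }

  std::vector<long> active;
  std::vector<double> delta, denom;
  std::vector<int> az, ay, ax;
  double rms = NA_REAL;
  int iter = 0, still = 0;  // consecutive iterations with a stationary front
  const double eps = 1e-12;

  for (iter = 0; iter < max_iter; ++iter) {
    // rebuild the active band
    active.clear(); az.clear(); ay.clear(); ax.clear();
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          const long i = IDX(z, y, x, nz, ny);
          if (std::fabs(phi[i]) <= band) {
            active.push_back(i); az.push_back(z); ay.push_back(y); ax.push_back(x);
          }
        }
    if (active.empty()) break;
    const size_t na = active.size();
    delta.assign(na, 0.0);
    denom.assign(na, 0.0);

    for (size_t k = 0; k < na; ++k) {
      const int z = az[k], y = ay[k], x = ax[k];
      const long i = active[k];
      const int zp = z + 1 < nz ? z + 1 : z, zm = z > 0 ? z - 1 : z;
      const int yp = y + 1 < ny ? y + 1 : y, ym = y > 0 ? y - 1 : y;
      const int xp = x + 1 < nx ? x + 1 : x, xm = x > 0 ? x - 1 : x;
      const double p = phi[i];
      const double pzp = phi[IDX(zp, y, x, nz, ny)], pzm = phi[IDX(zm, y, x, nz, ny)];
      const double pyp = phi[IDX(z, yp, x, nz, ny)], pym = phi[IDX(z, ym, x, nz, ny)];
      const double pxp = phi[IDX(z, y, xp, nz, ny)], pxm = phi[IDX(z, y, xm, nz, ny)];

      const double Dzp = (pzp - p) / hz, Dzm = (p - pzm) / hz;
      const double Dyp = (pyp - p) / hy, Dym = (p - pym) / hy;
      const double Dxp = (pxp - p) / hx, Dxm = (p - pxm) / hx;
      const double Dz = 0.5 * (Dzp + Dzm), Dy = 0.5 * (Dyp + Dym), Dx = 0.5 * (Dxp + Dxm);

      double dphi = 0.0, den = 0.0;
      const double gi = g[i];

      // propagation (outward, F = prop * g >= 0): upwind gradient
      if (prop > 0.0) {
        const double gp = std::sqrt(
          std::max(Dzm, 0.0) * std::max(Dzm, 0.0) + std::min(Dzp, 0.0) * std::min(Dzp, 0.0) +
          std::max(Dym, 0.0) * std::max(Dym, 0.0) + std::min(Dyp, 0.0) * std::min(Dyp, 0.0) +
          std::max(Dxm, 0.0) * std::max(Dxm, 0.0) + std::min(Dxp, 0.0) * std::min(Dxp, 0.0));
        dphi += -prop * gi * gp;
        // CFL bound with the speed bound (g <= 1), not the local g: low-speed
        // voxels must advance slowly in absolute terms, not merely relative
        // to their own (cancelled) denominator.
        den += prop * (1.0 / hz + 1.0 / hy + 1.0 / hx);
      }

      // curvature smoothing
      if (curv > 0.0) {
        const double Dzz = (pzp - 2.0 * p + pzm) / (hz * hz);
        const double Dyy = (pyp - 2.0 * p + pym) / (hy * hy);
        const double Dxx = (pxp - 2.0 * p + pxm) / (hx * hx);
        const double Dzy = (phi[IDX(zp, yp, x, nz, ny)] - phi[IDX(zp, ym, x, nz, ny)]
                          - phi[IDX(zm, yp, x, nz, ny)] + phi[IDX(zm, ym, x, nz, ny)])
                          / ((zp - zm) * (yp - ym) * hz * hy + eps);
        const double Dzx = (phi[IDX(zp, y, xp, nz, ny)] - phi[IDX(zp, y, xm, nz, ny)]
                          - phi[IDX(zm, y, xp, nz, ny)] + phi[IDX(zm, y, xm, nz, ny)])
                          / ((zp - zm) * (xp - xm) * hz * hx + eps);
        const double Dyx = (phi[IDX(z, yp, xp, nz, ny)] - phi[IDX(z, yp, xm, nz, ny)]
                          - phi[IDX(z, ym, xp, nz, ny)] + phi[IDX(z, ym, xm, nz, ny)])
                          / ((yp - ym) * (xp - xm) * hy * hx + eps);
        const double g2 = Dz * Dz + Dy * Dy + Dx * Dx;
        if (g2 > eps) {
          const double kappa = (Dzz * (Dy * Dy + Dx * Dx) + Dyy * (Dz * Dz + Dx * Dx)
                              + Dxx * (Dz * Dz + Dy * Dy)
                              - 2.0 * (Dz * Dy * Dzy + Dz * Dx * Dzx + Dy * Dx * Dyx))
                              / std::pow(g2, 1.5);
          dphi += curv * gi * kappa * std::sqrt(g2);
        }
        den += 2.0 * curv * (1.0 / (hz * hz) + 1.0 / (hy * hy) + 1.0 / (hx * hx));
      }

      // advection towards edges: v = adv * grad g, v > 0 uses forward difference
      if (adv > 0.0) {
        const double vz = adv * gz[i], vy = adv * gy[i], vx = adv * gx[i];
        dphi += vz > 0.0 ? vz * Dzp : vz * Dzm;
        dphi += vy > 0.0 ? vy * Dyp : vy * Dym;
        dphi += vx > 0.0 ? vx * Dxp : vx * Dxm;
        den += std::fabs(vz) / hz + std::fabs(vy) / hy + std::fabs(vx) / hx;
      }

      delta[k] = dphi;
      denom[k] = den;
    }

    // Local time stepping: each band voxel advances with its own CFL-bounded
    // step.  The transient is not a single global time step, but the front
    // converges to the same pinned steady state (where the terms balance)
    // and growth far from edges is not starved by the stiff advection term
    // at already-pinned front segments.
    double ss = 0.0;
    bool any = false;
    long flips = 0;
    for (size_t k = 0; k < na; ++k) {
      if (denom[k] <= eps) continue;
      any = true;
      double u = (0.45 / denom[k]) * delta[k];
      // never move more than half the finest grid step per iteration, so the
      // front cannot tunnel through a thin low-speed shell
      if (u > 0.45) u = 0.45; else if (u < -0.45) u = -0.45;
      const double before = phi[active[k]];
      phi[active[k]] += u;
      if ((before < 0.0) != (phi[active[k]] < 0.0)) ++flips;
      ss += u * u;
    }
    if (!any) break;
    rms = std::sqrt(ss / (double)na);
    // stationary when no more than 0.01% of band voxels crossed the interface
    if (flips <= (long)(na / 10000)) ++still; else still = 0;
    if (iter >= 5 && (rms < rms_tol || still >= 25)) { ++iter; break; }

    if (reinit_every > 0 && (iter + 1) % reinit_every == 0) {
      // Reinitialize to a signed distance from the current zero level while
      // preserving its subvoxel position: voxels next to a sign change get
      // a linearly interpolated distance to the interface, and the distance
      // transform is seeded with those values (binary reinitialization
      // quantizes the front to voxel centers and makes it drift).
      std::vector<double> a((size_t)N, DT_BIG);
      const double heps = 1e-12;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            const long i = IDX(z, y, x, nz, ny);
            const double p = phi[i];
            double dmin = DT_BIG;
            const long nb[6] = {
              z > 0 ? IDX(z - 1, y, x, nz, ny) : -1,
              z + 1 < nz ? IDX(z + 1, y, x, nz, ny) : -1,
              y > 0 ? IDX(z, y - 1, x, nz, ny) : -1,
              y + 1 < ny ? IDX(z, y + 1, x, nz, ny) : -1,
              x > 0 ? IDX(z, y, x - 1, nz, ny) : -1,
              x + 1 < nx ? IDX(z, y, x + 1, nz, ny) : -1 };
            const double hh[6] = { hz, hz, hy, hy, hx, hx };
            for (int t = 0; t < 6; ++t) {
              if (nb[t] < 0) continue;
              const double q = phi[nb[t]];
              if ((p < 0.0) != (q < 0.0)) {
                const double dd = hh[t] * std::fabs(p) / (std::fabs(p) + std::fabs(q) + heps);
                if (dd < dmin) dmin = dd;
              }
            }
            if (dmin < DT_BIG) a[i] = dmin * dmin;
          }
      edt3d_sq(a, nz, ny, nx, hz, hy, hx);
      for (long i = 0; i < N; ++i)
        phi[i] = (phi[i] < 0.0 ? -1.0 : 1.0) * std::sqrt(a[i]);
    }
  }

  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = dim;
  return List::create(_["phi"] = out, _["iterations"] = iter, _["rms"] = rms);
}
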