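#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Velocity array layout matches the R side: dim = (nt, nz, ny, nx, 3),
// stored in cm/s. World coordinates are mm with the voxel-center
// convention: world x of grid column i (0-based here) is ox + i*dx.
// Time is periodic with period nt*td (ms). Samples are returned in
// mm/ms (1 mm/ms == 100 cm/s).

namespace {

struct Grid {
  const double* v;
  int nt, nz, ny, nx;
  double dx, dy, dz, ox, oy, oz, td;
};

inline R_xlen_t gidx(const Grid& g, int t, int z, int y, int x, int c) {
  return (R_xlen_t)t +
         (R_xlen_t)g.nt * ((R_xlen_t)z +
         (R_xlen_t)g.nz * ((R_xlen_t)y +
         (R_xlen_t)g.ny * ((R_xlen_t)x + (R_xlen_t)g.nx * (R_xlen_t)c)));
}

// periodic reduction into [0, p); floor-based so the modulo of negative
// times lands in-range
inline double pmod(double x, double p) {
  double r = x - p * std::floor(x / p);
  if (r >= p) r -= p;
  return r;
}

inline bool inside(const Grid& g, double X, double Y, double Z) {
  const double fx = (X - g.ox) / g.dx;
  const double fy = (Y - g.oy) / g.dy;
  const double fz = (Z - g.oz) / g.dz;
  return fx >= 0.0 && fx <= g.nx - 1.0 &&
         fy >= 0.0 && fy <= g.ny - 1.0 &&
         fz >= 0.0 && fz <= g.nz - 1.0;
}

// Trilinear in space, linear in time (periodic across the cycle
// boundary). Returns false when the position lies outside the
// voxel-center bounding box; *out is then untouched.
inline bool sampleVel(const Grid& g, double X, double Y, double Z,
                      double tms, double* out) {
  const double fx = (X - g.ox) / g.dx;
  const double fy = (Y - g.oy) / g.dy;
  const double fz = (Z - g.oz) / g.dz;
  if (!(fx >= 0.0 && fx <= g.nx - 1.0 &&
        fy >= 0.0 && fy <= g.ny - 1.0 &&
        fz >= 0.0 && fz <= g.nz - 1.0))
    return false;

  const double cyc = g.nt * g.td;
  const double tt = pmod(tms, cyc);
  double ft = tt / g.td;
  int t0 = (int)std::floor(ft);
  if (t0 >= g.nt) t0 = g.nt - 1;  // guards fmod rounding at the seam
  const double wt = ft - t0;
  const int t1 = (t0 + 1) % g.nt;

  int x0 = (int)std::floor(fx); if (x0 > g.nx - 2) x0 = g.nx - 2;
  int y0 = (int)std::floor(fy); if (y0 > g.ny - 2) y0 = g.ny - 2;
  int z0 = (int)std::floor(fz); if (z0 > g.nz - 2) z0 = g.nz - 2;
  const double wx = fx - x0, wy = fy - y0, wz = fz - z0;

  double w8[8];
  int cz[8], cy[8], cx[8];
  int k = 0;
  for (int dz2 = 0; dz2 < 2; ++dz2)
    for (int dy2 = 0; dy2 < 2; ++dy2)
      for (int dx2 = 0; dx2 < 2; ++dx2) {
        w8[k] = (dz2 ? wz : 1.0 - wz) * (dy2 ? wy : 1.0 - wy) *
                (dx2 ? wx : 1.0 - wx);
        cz[k] = z0 + dz2; cy[k] = y0 + dy2; cx[k] = x0 + dx2;
        ++k;
      }

  for (int c = 0; c < 3; ++c) {
    double a0 = 0.0, a1 = 0.0;
    for (int j = 0; j < 8; ++j) {
      a0 += w8[j] * g.v[gidx(g, t0, cz[j], cy[j], cx[j], c)];
      a1 += w8[j] * g.v[gidx(g, t1, cz[j], cy[j], cx[j], c)];
    }
    out[c] = 0.01 * ((1.0 - wt) * a0 + wt * a1);  // cm/s -> mm/ms
  }
  return true;
}

inline Grid makeGrid(const NumericVector& vel, const IntegerVector& dims,
                     const NumericVector& spacing,
                     const NumericVector& origin, double td) {
  Grid g;
  g.v = REAL(vel);
  g.nt = dims[0]; g.nz = dims[1]; g.ny = dims[2]; g.nx = dims[3];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.td = td;
  return g;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sample_velocity_cpp(NumericVector vel, IntegerVector dims,
                                  NumericVector spacing,
                                  NumericVector origin, double td,
                                  NumericMatrix pos, NumericVector tms) {
  const Grid g = makeGrid(vel, dims, spacing, origin, td);
  const int n = pos.nrow();
  NumericMatrix out(n, 3);
  double u[3];
  for (int i = 0; i < n; ++i) {
    const double t = (tms.size() == 1) ? tms[0] : tms[i];
    if (sampleVel(g, pos(i, 0), pos(i, 1), pos(i, 2), t, u)) {
      out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
    } else {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
    }
  }
  return out;
}

// Classic fixed-step RK4 pathline integration. `dir` is +1 (forward in
// time) or -1 (backward); `duration` (ms) is always positive and the
// final partial step is shortened so trajectories end exactly at
// t_start + dir*duration. A particle whose update (or any RK4 stage)
// leaves the voxel-center bounding box is frozen at its last in-grid
// position and flagged.
// [[Rcpp::export]]
List trace_cpp(NumericVector vel, IntegerVector dims, NumericVector spacing,
               NumericVector origin, double td, NumericMatrix seeds,
               double t_start, double duration, int dir, double dt,
               bool record) {
  const Grid g = makeGrid(vel, dims, spacing, origin, td);
  const int n = seeds.nrow();

  int nfull = (int)std::floor(duration / dt + 1e-9);
  double rem = duration - nfull * dt;
  if (rem < 1e-9) rem = 0.0;
  const int nsteps = nfull + (rem > 0.0 ? 1 : 0);

  NumericMatrix posm(n, 3);
  IntegerVector status(n);  // 0 = active, 1 = left_grid
  for (int i = 0; i < n; ++i) {
    posm(i, 0) = seeds(i, 0); posm(i, 1) = seeds(i, 1);
    posm(i, 2) = seeds(i, 2);
    status[i] = inside(g, seeds(i, 0), seeds(i, 1), seeds(i, 2)) ? 0 : 1;
  }

  NumericVector traj;
  if (record) {
    traj = NumericVector((R_xlen_t)(nsteps + 1) * n * 3);
    traj.attr("dim") = IntegerVector::create(nsteps + 1, n, 3);
  }
  NumericVector times(nsteps + 1);
  times[0] = t_start;

  if (record)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        traj[(R_xlen_t)0 + (R_xlen_t)(nsteps + 1) * (i + (R_xlen_t)n * c)] =
            posm(i, c);

  double t = t_start;
  double k1[3], k2[3], k3[3], k4[3];
  for (int s = 0; s < nsteps; ++s) {
    const double h = (s < nfull) ? dt : rem;
    const double sh = dir * h;
    for (int i = 0; i < n; ++i) {
      if (status[i] != 0) continue;
      const double x = posm(i, 0), y = posm(i, 1), z = posm(i, 2);
      bool ok = sampleVel(g, x, y, z, t, k1);
      ok = ok && sampleVel(g, x + 0.5 * sh * k1[0], y + 0.5 * sh * k1[1],
                           z + 0.5 * sh * k1[2], t + 0.5 * sh, k2);
      ok = ok && sampleVel(g, x + 0.5 * sh * k2[0], y + 0.5 * sh * k2[1],
                           z + 0.5 * sh * k2[2], t + 0.5 * sh, k3);
      ok = ok && sampleVel(g, x + sh * k3[0], y + sh * k3[1],
                           z + sh * k3[2], t + sh, k4);
      if (ok) {
        const double nx_ = x + sh / 6.0 * (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]);
        const double ny_ = y + sh / 6.0 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]);
        const double nz_ = z + sh / 6.0 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]);
        if (inside(g, nx_, ny_, nz_)) {
          posm(i, 0) = nx_; posm(i, 1) = ny_; posm(i, 2) = nz_;
        } else {
          status[i] = 1;
        }
      } else {
        status[i] = 1;
      }
    }
    t += sh;
    times[s + 1] = t;
    if (record)
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          traj[(R_xlen_t)(s + 1) +
               (R_xlen_t)(nsteps + 1) * (i + (R_xlen_t)n * c)] = posm(i, c);
  }

  return List::create(_["positions"] = posm, _["status"] = status,
                      _["times"] = times,
                      _["trajectories"] = record ? (SEXP)traj : R_NilValue);
}
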