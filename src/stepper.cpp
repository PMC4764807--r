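#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Field kind codes shared with R/fields.R: 0 NONE, 1 PDCEF, 2 ACEF, 3 CPEF.
// PDCEF: E0 along x during the first `dpulse` time units of each period
// 2*pi/om (phase acts as a time offset). ACEF: E0*cos(om*t + phase) along x.
// CPEF: amplitude E0 rotating in the xy-plane.
static inline void eval_field(const int kind, const double E0, const double om,
                              const double dpulse, const double phase,
                              const double t, double &Ex, double &Ey,
                              double &Ez) {
  Ex = Ey = Ez = 0.0;
  if (kind == 1) {
    const double T = 2.0 * M_PI / om;
    const double s = t + phase;
    double tau = s - std::floor(s / T) * T;  // s mod T, in [0, T)
    if (tau < dpulse) Ex = E0;
  } else if (kind == 2) {
    Ex = E0 * std::cos(om * t + phase);
  } else if (kind == 3) {
    Ex = E0 * std::cos(om * t + phase);
    Ey = E0 * std::sin(om * t + phase);
  }
}

// [[Rcpp::export]]
NumericVector field_vector_cpp(int kind, double E0, double om, double dpulse,
                               double phase, NumericVector t) {
  const int n = t.size();
  NumericVector out(3 * n);
  out.attr("dim") = Dimension(n, 3);
  for (int s = 0; s < n; ++s) {
    double Ex, Ey, Ez;
    eval_field(kind, E0, om, dpulse, phase, t[s], Ex, Ey, Ez);
    out[s] = Ex;
    out[n + s] = Ey;
    out[2 * n + s] = Ez;
  }
  return out;
}

// Diffusion + electric-field forcing rate:
//   (1/phi) div(phi grad u) + (1/phi) (grad phi . E)
// in conservative (flux) form with 2-point face averages of phi, mirrored
// ghost layers at the outer box (no-flux), and gx,gy,gz = (grad phi)/phi
// precomputed on the grid.  Points flagged inactive (phi below the floor)
// get rate 0 and are held at rest by the stepper.
// [[Rcpp::export]]
NumericVector rate_field_cpp(NumericVector u, NumericVector phi,
                             NumericVector invphi, NumericVector gx,
                             NumericVector gy, NumericVector gz,
                             IntegerVector active, IntegerVector dims,
                             double dx, double Ex, double Ey, double Ez) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = 1, sy = nx, sz = nx * ny;
  const double idx2 = 1.0 / (dx * dx);
  NumericVector out(u.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        if (!active[idx]) {
          out[idx] = 0.0;
          continue;
        }
        const double uc = u[idx], pc = phi[idx];
        // faces to held-at-rest (inactive) points carry no flux
        double lap = 0.0;
        if (i > 0 && active[idx - sx])
          lap += 0.5 * (pc + phi[idx - sx]) * (u[idx - sx] - uc);
        if (i < nx - 1 && active[idx + sx])
          lap += 0.5 * (pc + phi[idx + sx]) * (u[idx + sx] - uc);
        if (j > 0 && active[idx - sy])
          lap += 0.5 * (pc + phi[idx - sy]) * (u[idx - sy] - uc);
        if (j < ny - 1 && active[idx + sy])
          lap += 0.5 * (pc + phi[idx + sy]) * (u[idx + sy] - uc);
        if (k > 0 && active[idx - sz])
          lap += 0.5 * (pc + phi[idx - sz]) * (u[idx - sz] - uc);
        if (k < nz - 1 && active[idx + sz])
          lap += 0.5 * (pc + phi[idx + sz]) * (u[idx + sz] - uc);
        out[idx] = lap * idx2 * invphi[idx] + gx[idx] * Ex + gy[idx] * Ey +
                   gz[idx] * Ez;
      }
    }
  }
  return out;
}

// Explicit Euler integration of the Barkley medium for nsteps steps.
// u <- u + dt * ( (1/eps) u (1-u) (u - (v+b)/a) + diffusion + forcing )
// v <- v + dt * (u - v)                     (old u on the right-hand side)
// Probes (0-based linear indices) are sampled from the updated u every
// `probe_every` steps.  Returns updated u, v, probe matrix and max |u|.
// [[Rcpp::export]]
List advance_cpp(NumericVector u0, NumericVector v0, NumericVector phi,
                 NumericVector invphi, NumericVector gx, NumericVector gy,
                 NumericVector gz, IntegerVector active, IntegerVector dims,
                 double a, double b, double eps, double dx, double dt,
                 int kind, double E0, double om, double dpulse, double phase,
                 double t0, int nsteps, IntegerVector probe_idx,
                 int probe_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = 1, sy = nx, sz = nx * ny;
  const R_xlen_t n = u0.size();
  const double idx2 = 1.0 / (dx * dx);
  const double ieps = 1.0 / eps;

  std::vector<double> Ubuf(u0.begin(), u0.end());
  std::vector<double> Unbuf(n, 0.0);
  std::vector<double> Vbuf(v0.begin(), v0.end());
  double *__restrict__ U = Ubuf.data();
  double *__restrict__ Un = Unbuf.data();
  double *__restrict__ V = Vbuf.data();
  const double *__restrict__ P = REAL(phi);
  const double *__restrict__ IP = REAL(invphi);
  const double *__restrict__ GX = REAL(gx);
  const double *__restrict__ GY = REAL(gy);
  const double *__restrict__ GZ = REAL(gz);
  const int *__restrict__ ACT = INTEGER(active);
  const double inv_a = 1.0 / a;

  // Points below the phase-field floor are held at rest: with u = v = 0,
  // invphi = 0 and (grad phi)/phi = 0 there, the update below keeps them
  // at exactly 0 without a branch, so the mask is applied once on entry.
  for (R_xlen_t q = 0; q < n; ++q) {
    if (!ACT[q]) {
      U[q] = 0.0;
      V[q] = 0.0;
    }
  }

  // Per grid row (fixed j,k): index range [ia, ib] where the medium is
  // non-uniform (phi != 1 or forcing coefficients nonzero).  Outside the
  // band the update reduces to the plain 7-point Laplacian + kinetics,
  // which reads only U and V -- much lighter on memory bandwidth.
  const int nrows = ny * nz;
  std::vector<unsigned char> mask(n, 0);
  for (R_xlen_t q = 0; q < n; ++q) {
    mask[q] = (P[q] != 1.0 || IP[q] != 1.0 || GX[q] != 0.0 ||
               GY[q] != 0.0 || GZ[q] != 0.0);
  }
  // dilate by one cell: a uniform point bordering the band still needs
  // the phi-face fluxes of the generic update
  std::vector<unsigned char> mask2(mask);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        if (i > 0) mask2[idx - sx] = 1;
        if (i < nx - 1) mask2[idx + sx] = 1;
        if (j > 0) mask2[idx - sy] = 1;
        if (j < ny - 1) mask2[idx + sy] = 1;
        if (k > 0) mask2[idx - sz] = 1;
        if (k < nz - 1) mask2[idx + sz] = 1;
      }
    }
  }
  std::vector<int> band_lo(nrows), band_hi(nrows);
  for (int r = 0; r < nrows; ++r) {
    const int base = r * nx;
    int lo = nx, hi = -1;
    for (int i = 0; i < nx; ++i) {
      if (mask2[base + i]) {
        if (i < lo) lo = i;
        hi = i;
      }
    }
    band_lo[r] = lo;
    band_hi[r] = hi;
  }

  const int nprobe = probe_idx.size();
  const int nrec = (probe_every > 0) ? nsteps / probe_every : 0;
  NumericMatrix probes(nrec, nprobe);
  NumericVector probe_t(nrec);
  int rec = 0;
  double maxabs = 0.0;

  for (int step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;
    double Ex, Ey, Ez;
    eval_field(kind, E0, om, dpulse, phase, t, Ex, Ey, Ez);
    for (int k = 0; k < nz; ++k) {
      const int offzm = (k > 0) ? -sz : 0;       // mirrored ghosts: a
      const int offzp = (k < nz - 1) ? sz : 0;   // clamped neighbor gives
      for (int j = 0; j < ny; ++j) {             // zero boundary flux
        const int offym = (j > 0) ? -sy : 0;
        const int offyp = (j < ny - 1) ? sy : 0;
        const int r = j + ny * k;
        const int base = nx * r;

        // generic (phase-field) update for one point; faces to
        // held-at-rest (inactive) points carry no flux
        auto generic = [&](const int i) {
          const int idx = i + base;
          const int offxm = (i > 0) ? -sx : 0;
          const int offxp = (i < nx - 1) ? sx : 0;
          const double uc = U[idx], vc = V[idx], pc = P[idx];
          double lap = ACT[idx + offxm] * 0.5 * (pc + P[idx + offxm]) *
                       (U[idx + offxm] - uc);
          lap += ACT[idx + offxp] * 0.5 * (pc + P[idx + offxp]) *
                 (U[idx + offxp] - uc);
          lap += ACT[idx + offym] * 0.5 * (pc + P[idx + offym]) *
                 (U[idx + offym] - uc);
          lap += ACT[idx + offyp] * 0.5 * (pc + P[idx + offyp]) *
                 (U[idx + offyp] - uc);
          lap += ACT[idx + offzm] * 0.5 * (pc + P[idx + offzm]) *
                 (U[idx + offzm] - uc);
          lap += ACT[idx + offzp] * 0.5 * (pc + P[idx + offzp]) *
                 (U[idx + offzp] - uc);
          const double du =
              ieps * uc * (1.0 - uc) * (uc - (vc + b) * inv_a);
          Un[idx] = uc + dt * (du + lap * idx2 * IP[idx] + GX[idx] * Ex +
                               GY[idx] * Ey + GZ[idx] * Ez);
          V[idx] = vc + dt * (uc - vc);
        };
        // uniform-medium fast update over [i0, i1], interior in x
        auto fast_run = [&](const int i0, const int i1) {
          const double *__restrict__ u = U;
          double *__restrict__ un = Un;
          double *__restrict__ vv = V;
          const double *__restrict__ um = U + offym;
          const double *__restrict__ up = U + offyp;
          const double *__restrict__ zm = U + offzm;
          const double *__restrict__ zp = U + offzp;
          for (int i = i0; i <= i1; ++i) {
            const int idx = i + base;
            const double uc = u[idx], vc = vv[idx];
            const double lap = u[idx - 1] + u[idx + 1] + um[idx] + up[idx] +
                               zm[idx] + zp[idx] - 6.0 * uc;
            const double du =
                ieps * uc * (1.0 - uc) * (uc - (vc + b) * inv_a);
            un[idx] = uc + dt * (du + lap * idx2);
            vv[idx] = vc + dt * (uc - vc);
          }
        };

        generic(0);
        int A = band_lo[r], B = band_hi[r];
        if (B < 0) {  // row entirely uniform
          fast_run(1, nx - 2);
        } else {
          if (A < 1) A = 1;
          if (B > nx - 2) B = nx - 2;
          fast_run(1, A - 1);
          for (int i = A; i <= B; ++i) generic(i);
          fast_run(B + 1, nx - 2);
        }
        generic(nx - 1);
      }
    }
    // separate vectorizable reduction: running max |u| and finiteness
    double stepmax = 0.0;
    int allfin = 1;
    for (R_xlen_t q = 0; q < n; ++q) {
      const double au = std::fabs(Un[q]);
      if (au > stepmax) stepmax = au;
      allfin &= (int)(au < HUGE_VAL);
    }
    if (stepmax > maxabs) maxabs = stepmax;
    if (!allfin || !std::isfinite(stepmax)) {
      for (R_xlen_t q = 0; q < n; ++q) {
        if (!std::isfinite(Un[q])) {
          const int bi = (int)(q % nx), bj = (int)((q / nx) % ny),
                    bk = (int)(q / ((R_xlen_t)nx * ny));
          stop("numerical instability: non-finite u at grid index (%d, %d, %d) "
               "at t = %g",
               bi + 1, bj + 1, bk + 1, t + dt);
        }
      }
    }
    std::swap(U, Un);
    if (probe_every > 0 && ((step + 1) % probe_every == 0) && rec < nrec) {
      probe_t[rec] = t0 + (step + 1) * dt;
      for (int p = 0; p < nprobe; ++p) probes(rec, p) = U[probe_idx[p]];
      ++rec;
    }
  }

  NumericVector uout(n), vout(n);
  std::copy(U, U + n, uout.begin());
  std::copy(V, V + n, vout.begin());
  return List::create(_["u"] = uout, _["v"] = vout, _["probe_t"] = probe_t,
                      _["probe_u"] = probes, _["max_abs_u"] = maxabs);
}
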