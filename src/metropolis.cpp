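#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Truncated-and-shifted 12-6 pair potential plus an optional layering field
// w(z); single-particle Metropolis moves with minimum-image distances in an
// orthorhombic box. Uses R's RNG so set.seed() gives reproducible output.

static inline double pair_u(double r2, double eps, double sig2,
                            double cut2, double ushift) {
  if (r2 >= cut2) return 0.0;
  double s6 = sig2 / r2;
  s6 = s6 * s6 * s6;
  return 4.0 * eps * (s6 * s6 - s6) - ushift;
}

// field_type: 0 none, 1 harmonic 0.5*k*z'^2 (p1=k), 2 cosine A*cos(3*pi*z'/h)
// inside |z'| < h/2 (p1=A, p2=h); z' is the z offset from the box midplane,
// minimum-imaged.
static inline double field_w(double z, double Lz, int field_type,
                             double p1, double p2) {
  if (field_type == 0) return 0.0;
  double zp = z - 0.5 * Lz;
  zp -= Lz * std::round(zp / Lz);
  if (field_type == 1) return 0.5 * p1 * zp * zp;
  if (std::fabs(zp) < 0.5 * p2) return p1 * std::cos(3.0 * M_PI * zp / p2);
  return 0.0;
}

static double particle_energy(int i, const std::vector<double>& x,
                              const std::vector<double>& y,
                              const std::vector<double>& z, int n,
                              double Lx, double Ly, double Lz,
                              double eps, double sig2, double cut2,
                              double ushift, int field_type, double p1,
                              double p2) {
  double e = field_w(z[i], Lz, field_type, p1, p2);
  if (eps > 0.0) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j]; dx -= Lx * std::round(dx / Lx);
      double dy = y[i] - y[j]; dy -= Ly * std::round(dy / Ly);
      double dz = z[i] - z[j]; dz -= Lz * std::round(dz / Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      e += pair_u(r2, eps, sig2, cut2, ushift);
    }
  }
  return e;
}

// [[Rcpp::export]]
List mc_kernel(NumericMatrix coords0, NumericVector box, double epsilon,
               double sigma, double cutoff, int field_type, double fp1,
               double fp2, double kT, int n_sweeps, double step_size,
               int burnin_sweeps, int frame_stride) {
  const int n = coords0.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double sig2 = sigma * sigma, cut2 = cutoff * cutoff;
  double s6 = std::pow(sigma / cutoff, 6.0);
  const double ushift = 4.0 * epsilon * (s6 * s6 - s6);

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
  }

  int n_rec = 0;
  if (frame_stride > 0 && n_sweeps > burnin_sweeps)
    n_rec = (n_sweeps - burnin_sweeps) / frame_stride;
  NumericVector frames(static_cast<R_xlen_t>(n_rec) * n * 3);
  IntegerVector rec_sweeps(n_rec);

  long long accepted = 0, attempted = 0;
  int rec = 0;
  RNGScope scope;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i = static_cast<int>(unif_rand() * n);
      if (i == n) i = n - 1;
      double e_old = particle_energy(i, x, y, z, n, Lx, Ly, Lz, epsilon, sig2,
                                     cut2, ushift, field_type, fp1, fp2);
      double ox = x[i], oy = y[i], oz = z[i];
      x[i] += (unif_rand() - 0.5) * 2.0 * step_size;
      y[i] += (unif_rand() - 0.5) * 2.0 * step_size;
      z[i] += (unif_rand() - 0.5) * 2.0 * step_size;
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      z[i] -= Lz * std::floor(z[i] / Lz);
      double e_new = particle_energy(i, x, y, z, n, Lx, Ly, Lz, epsilon, sig2,
                                     cut2, ushift, field_type, fp1, fp2);
      if (!std::isfinite(e_new) || !std::isfinite(e_old))
        stop("non-finite energy in Metropolis sampler");
      ++attempted;
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
        ++accepted;
      } else {
        x[i] = ox; y[i] = oy; z[i] = oz;
      }
    }
    if (sweep > burnin_sweeps && frame_stride > 0 &&
        (sweep - burnin_sweeps) % frame_stride == 0 && rec < n_rec) {
      R_xlen_t base = static_cast<R_xlen_t>(rec) * n * 3;
      for (int i = 0; i < n; ++i) {
        frames[base + i] = x[i];
        frames[base + n + i] = y[i];
        frames[base + 2 * n + i] = z[i];
      }
      rec_sweeps[rec] = sweep;
      ++rec;
    }
  }
  return List::create(_["frames"] = frames, _["n_recorded"] = rec,
                      _["rec_sweeps"] = rec_sweeps,
                      _["accepted"] = static_cast<double>(accepted),
                      _["attempted"] = static_cast<double>(attempted));
}
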