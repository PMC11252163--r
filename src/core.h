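#pragma once

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>

// SPC/Fw force-field parameters (units: A, kcal/mol, e, rad).
struct Spcfw {
  double l0;     // O-H equilibrium bond length
  double kb;     // bond stiffness, U = kb/2 (l - l0)^2
  double th0;    // H-O-H equilibrium angle (rad)
  double ka;     // bend stiffness, U = ka/2 (th - th0)^2
  double eps;    // LJ well depth (O-O)
  double sigma;  // LJ size (O-O)
  double qO, qH; // partial charges (e)
  double kc;     // Coulomb prefactor, kcal*A/mol/e^2
};

inline Spcfw spcfw_from_list(Rcpp::List p) {
  Spcfw s;
  s.l0 = p["bond_equilibrium_length"];
  s.kb = p["bond_stiffness"];
  s.th0 = p["bend_equilibrium_angle"];
  s.ka = p["bend_stiffness"];
  s.eps = p["lj_epsilon"];
  s.sigma = p["lj_sigma"];
  s.qO = p["charge_O"];
  s.qH = p["charge_H"];
  s.kc = p["coulomb_prefactor"];
  return s;
}

// Ewald splitting/truncation settings for the per-molecule-pair lattice sum.
struct EwaldPars {
  double L;      // box side
  double alpha;  // splitting parameter (1/A)
  int kmax;      // reciprocal cutoff in integer shells, |m| <= kmax
  int nreal;     // real-space image cutoff in integer shells
};

// Cached reciprocal-space table: wave vectors of one half-space (k and -k
// combined into a factor 2) inside the spherical cutoff, with Gaussian
// coefficients 4*pi*exp(-k^2/(4 alpha^2))/(k^2 V).
struct KTable {
  double L = -1.0, alpha = -1.0;
  int kmax = -1;
  std::vector<double> kx, ky, kz, coef;
  std::vector<int> mx, my, mz;  // integer indices, k = 2 pi m / L
  void build(double L_, double alpha_, int kmax_);
};

const KTable& ktable_get(double L, double alpha, int kmax);

// per-atom phase factors e^{i 2 pi m x_d / L} for m = -kmax..kmax, three
// axes, stored as interleaved (re, im) pairs centred at index kmax
inline void phase_powers(const double* x, double L, int kmax,
                         double* out /* 3 * 2*(2*kmax+1) */) {
  const double twopi = 2.0 * M_PI;
  const int W = 2 * kmax + 1;
  for (int d = 0; d < 3; ++d) {
    double br = std::cos(twopi * x[d] / L), bi = std::sin(twopi * x[d] / L);
    double* row = out + d * 2 * W;
    double ar = 1.0, ai = 0.0;
    for (int m = 0; m <= kmax; ++m) {
      row[2 * (kmax + m)] = ar;
      row[2 * (kmax + m) + 1] = ai;
      row[2 * (kmax - m)] = ar;
      row[2 * (kmax - m) + 1] = -ai;
      double nr = ar * br - ai * bi;
      ai = ar * bi + ai * br;
      ar = nr;
    }
  }
}

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Periodic Coulomb interaction between two disjoint neutral charge groups
// (all periodic images included, no self terms, tinfoil boundaries).
// Positions are 3 x n column-major. Gradients are accumulated (+=).
double ewald_group_pair(const double* A, const double* qA, int nA,
                        const double* B, const double* qB, int nB,
                        const EwaldPars& ew, double kc,
                        double* gA, double* gB);

// Gradient and Hessian of the periodic charge kernel psi_E(r) (unit charges,
// no kc): grad filled with 3 entries, hess with 9 (column-major 3x3).
void ewald_kernel_derivs(const double* r, const EwaldPars& ew,
                         double* grad, double* hess);

// Bonded/LJ factor derivatives --------------------------------------------

// Harmonic bond between atoms at xa, xb (no imaging): returns energy,
// gradient on a in ga (gb = -ga).
inline double bond_energy_grad(const double* xa, const double* xb,
                               const Spcfw& p, double* ga) {
  double d[3] = {xa[0] - xb[0], xa[1] - xb[1], xa[2] - xb[2]};
  double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  double dr = r - p.l0;
  if (ga) {
    double f = p.kb * dr / r;
    ga[0] = f * d[0]; ga[1] = f * d[1]; ga[2] = f * d[2];
  }
  return 0.5 * p.kb * dr * dr;
}

// Harmonic bend at O between H1 and H2 (atom order O, H1, H2; no imaging).
// Gradients (3 each) on O, H1, H2.
inline double bend_energy_grad(const double* xo, const double* xh1,
                               const double* xh2, const Spcfw& p,
                               double* gO, double* gH1, double* gH2) {
  double u[3], w[3];
  double r1 = 0, r2 = 0, c = 0;
  for (int k = 0; k < 3; ++k) { u[k] = xh1[k] - xo[k]; w[k] = xh2[k] - xo[k]; }
  r1 = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  r2 = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  for (int k = 0; k < 3; ++k) { u[k] /= r1; w[k] /= r2; }
  c = u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  double s = std::sqrt(1.0 - c * c);
  if (s < 1e-12) s = 1e-12;  // collinear geometry: gradient direction degenerate
  double dU = p.ka * (th - p.th0);
  if (gO) {
    for (int k = 0; k < 3; ++k) {
      double g1 = -dU * (w[k] - c * u[k]) / (r1 * s);
      double g2 = -dU * (u[k] - c * w[k]) / (r2 * s);
      gH1[k] = g1;
      gH2[k] = g2;
      gO[k] = -(g1 + g2);
    }
  }
  return 0.5 * p.ka * (th - p.th0) * (th - p.th0);
}

// 12-6 Lennard-Jones under the minimum-image convention between two oxygens.
inline double lj_energy_grad(const double* xa, const double* xb, double L,
                             const Spcfw& p, double* ga) {
  double d[3];
  for (int k = 0; k < 3; ++k) d[k] = min_image(xa[k] - xb[k], L);
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  double r = std::sqrt(r2);
  double sr6 = std::pow(p.sigma * p.sigma / r2, 3.0);
  double sr12 = sr6 * sr6;
  if (ga) {
    // dU/dr = 4 eps (-12 sr12 + 6 sr6)/r ; grad_a = dU/dr * d/r
    double f = 4.0 * p.eps * (-12.0 * sr12 + 6.0 * sr6) / r2;
    ga[0] = f * d[0]; ga[1] = f * d[1]; ga[2] = f * d[2];
  }
  return 4.0 * p.eps * (sr12 - sr6);
}

// |dU_LJ/dr| at scalar separation r.
inline double lj_abs_dudr(double r, const Spcfw& p) {
  double sr6 = std::pow(p.sigma / r, 6.0);
  return std::fabs(4.0 * p.eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r);
}
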