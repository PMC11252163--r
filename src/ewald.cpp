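#include "core.h"
using namespace Rcpp;

static const double TWO_OVER_SQRT_PI = 1.1283791670955126;

void KTable::build(double L_, double alpha_, int kmax_) {
  L = L_; alpha = alpha_; kmax = kmax_;
  kx.clear(); ky.clear(); kz.clear(); coef.clear();
  mx.clear(); my.clear(); mz.clear();
  const double twopi = 2.0 * M_PI;
  const double V = L * L * L;
  const double pref = 4.0 * M_PI / V;
  const double k2max = (twopi * kmax / L) * (twopi * kmax / L);
  for (int ix = -kmax; ix <= kmax; ++ix) {
    for (int iy = -kmax; iy <= kmax; ++iy) {
      for (int iz = -kmax; iz <= kmax; ++iz) {
        // half-space: (iz > 0) or (iz == 0, iy > 0) or (iz == iy == 0, ix > 0)
        if (!(iz > 0 || (iz == 0 && iy > 0) || (iz == 0 && iy == 0 && ix > 0)))
          continue;
        double gx = twopi * ix / L, gy = twopi * iy / L, gz = twopi * iz / L;
        double k2 = gx * gx + gy * gy + gz * gz;
        if (k2 > k2max) continue;
        kx.push_back(gx); ky.push_back(gy); kz.push_back(gz);
        mx.push_back(ix); my.push_back(iy); mz.push_back(iz);
        coef.push_back(pref * std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
      }
    }
  }
}

const KTable& ktable_get(double L, double alpha, int kmax) {
  // small LRU-free cache: a handful of (L, alpha, kmax) combinations per run
  static std::vector<KTable> cache;
  for (auto& t : cache)
    if (t.L == L && t.alpha == alpha && t.kmax == kmax) return t;
  cache.emplace_back();
  cache.back().build(L, alpha, kmax);
  return cache.back();
}

typedef std::complex<double> cplx;

double ewald_group_pair(const double* A, const double* qA, int nA,
                        const double* B, const double* qB, int nB,
                        const EwaldPars& ew, double kc,
                        double* gA, double* gB) {
  const double L = ew.L, alpha = ew.alpha;
  double energy = 0.0;

  // real space: sum over atom pairs and image shells of erfc(alpha r)/r
  for (int a = 0; a < nA; ++a) {
    for (int b = 0; b < nB; ++b) {
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = min_image(A[3 * a + k] - B[3 * b + k], L);
      for (int nx = -ew.nreal; nx <= ew.nreal; ++nx)
        for (int ny = -ew.nreal; ny <= ew.nreal; ++ny)
          for (int nz = -ew.nreal; nz <= ew.nreal; ++nz) {
            double rv[3] = {d[0] + nx * L, d[1] + ny * L, d[2] + nz * L};
            double r2 = rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2];
            double r = std::sqrt(r2);
            double ar = alpha * r;
            double ef = std::erfc(ar);
            double qq = kc * qA[a] * qB[b];
            energy += qq * ef / r;
            if (gA) {
              double dfr = -(ef / r2 + TWO_OVER_SQRT_PI * alpha *
                                           std::exp(-ar * ar) / r) / r;
              for (int k = 0; k < 3; ++k) {
                double g = qq * dfr * rv[k];
                gA[3 * a + k] += g;
                gB[3 * b + k] -= g;
              }
            }
          }
    }
  }

  // reciprocal space via structure factors of the two groups (raw double
  // arithmetic: std::complex multiplies are not inlined by default)
  const KTable& kt = ktable_get(L, alpha, ew.kmax);
  const int K = (int)kt.kx.size();
  const int W = 2 * ew.kmax + 1;
  const int n = nA + nB;
  if (n > 16) Rcpp::stop("charge groups limited to 16 atoms");
  static thread_local std::vector<double> pw;
  pw.assign((size_t)n * 3 * 2 * W, 0.0);
  for (int a = 0; a < nA; ++a)
    phase_powers(A + 3 * a, L, ew.kmax, &pw[(size_t)a * 3 * 2 * W]);
  for (int b = 0; b < nB; ++b)
    phase_powers(B + 3 * b, L, ew.kmax, &pw[(size_t)(nA + b) * 3 * 2 * W]);

  double phr[16], phi[16];
  for (int i = 0; i < K; ++i) {
    const int ox = 2 * (ew.kmax + kt.mx[i]);
    const int oy = 2 * W + 2 * (ew.kmax + kt.my[i]);
    const int oz = 4 * W + 2 * (ew.kmax + kt.mz[i]);
    double SAr = 0, SAi = 0, SBr = 0, SBi = 0;
    for (int j = 0; j < n; ++j) {
      const double* p = &pw[(size_t)j * 3 * 2 * W];
      double xr = p[ox], xi = p[ox + 1];
      double yr = p[oy], yi = p[oy + 1];
      double zr = p[oz], zi = p[oz + 1];
      double tr = xr * yr - xi * yi, ti = xr * yi + xi * yr;
      double pr = tr * zr - ti * zi, pi = tr * zi + ti * zr;
      phr[j] = pr; phi[j] = pi;
      if (j < nA) { SAr += qA[j] * pr; SAi += qA[j] * pi; }
      else { SBr += qB[j - nA] * pr; SBi += qB[j - nA] * pi; }
    }
    double c2 = 2.0 * kc * kt.coef[i];
    energy += c2 * (SAr * SBr + SAi * SBi);
    if (gA) {
      // dE/dr_a = -c2 q_a Im[P_a S_B*] k ; dE/dr_b = -c2 q_b Im[P_b S_A*] k
      for (int a = 0; a < nA; ++a) {
        double im = phi[a] * SBr - phr[a] * SBi;
        double f = -c2 * qA[a] * im;
        gA[3 * a + 0] += f * kt.kx[i];
        gA[3 * a + 1] += f * kt.ky[i];
        gA[3 * a + 2] += f * kt.kz[i];
      }
      for (int b = 0; b < nB; ++b) {
        double im = phi[nA + b] * SAr - phr[nA + b] * SAi;
        double f = -c2 * qB[b] * im;
        gB[3 * b + 0] += f * kt.kx[i];
        gB[3 * b + 1] += f * kt.ky[i];
        gB[3 * b + 2] += f * kt.kz[i];
      }
    }
  }
  return energy;
}

void ewald_kernel_derivs(const double* r, const EwaldPars& ew,
                         double* grad, double* hess) {
  const double L = ew.L, alpha = ew.alpha;
  for (int k = 0; k < 3; ++k) grad[k] = 0.0;
  for (int k = 0; k < 9; ++k) hess[k] = 0.0;
  double d[3] = {min_image(r[0], L), min_image(r[1], L), min_image(r[2], L)};
  for (int nx = -ew.nreal; nx <= ew.nreal; ++nx)
    for (int ny = -ew.nreal; ny <= ew.nreal; ++ny)
      for (int nz = -ew.nreal; nz <= ew.nreal; ++nz) {
        double rv[3] = {d[0] + nx * L, d[1] + ny * L, d[2] + nz * L};
        double r2 = rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2];
        double rr = std::sqrt(r2);
        double ar = alpha * rr;
        double ef = std::erfc(ar);
        double ga = TWO_OVER_SQRT_PI * alpha * std::exp(-ar * ar);
        double fp = -(ef / r2 + ga / rr);                  // f'(r)
        double fpp = 2.0 * ef / (r2 * rr) +
                     ga * (2.0 / r2 + 2.0 * alpha * alpha); // f''(r)
        for (int i = 0; i < 3; ++i) {
          grad[i] += fp * rv[i] / rr;
          for (int j = 0; j < 3; ++j) {
            double rij = rv[i] * rv[j] / r2;
            hess[3 * j + i] += fpp * rij + (fp / rr) * ((i == j) - rij);
          }
        }
      }
  const KTable& kt = ktable_get(L, alpha, ew.kmax);
  for (size_t i = 0; i < kt.kx.size(); ++i) {
    double kv[3] = {kt.kx[i], kt.ky[i], kt.kz[i]};
    double kr = kv[0] * r[0] + kv[1] * r[1] + kv[2] * r[2];
    double c2 = 2.0 * kt.coef[i];
    double s = std::sin(kr), c = std::cos(kr);
    for (int a = 0; a < 3; ++a) {
      grad[a] -= c2 * s * kv[a];
      for (int b = 0; b < 3; ++b) hess[3 * b + a] -= c2 * c * kv[a] * kv[b];
    }
  }
}

// [[Rcpp::export(name = ".ewald_pair_cpp")]]
List ewald_pair_cpp(NumericMatrix posA, NumericVector qA, NumericMatrix posB,
                    NumericVector qB, double L, double alpha, int kmax,
                    int nreal, double kc, bool gradients = true) {
  int nA = posA.ncol(), nB = posB.ncol();
  if (posA.nrow() != 3 || posB.nrow() != 3)
    stop("positions must be 3 x n matrices");
  EwaldPars ew{L, alpha, kmax, nreal};
  NumericMatrix gA(3, nA), gB(3, nB);
  double e = ewald_group_pair(&posA[0], &qA[0], nA, &posB[0], &qB[0], nB, ew,
                              kc, gradients ? &gA[0] : nullptr,
                              gradients ? &gB[0] : nullptr);
  if (!gradients) return List::create(_["energy"] = e);
  return List::create(_["energy"] = e, _["grad_i"] = gA, _["grad_j"] = gB);
}

// Residual-field constants: bound on |grad psi_E - grad psi_bare(min image)|
// and on the Frobenius norm of the corresponding Hessian difference, taken
// over separations with |r| >= rmin. Used to turn nearest-image closed-form
// rate envelopes into envelopes for the full periodic interaction.
// [[Rcpp::export(name = ".ewald_rest_constants_cpp")]]
List ewald_rest_constants_cpp(double L, double alpha, int kmax, int nreal,
                              double rmin, int ngrid, int nrandom,
                              double margin) {
  EwaldPars ew{L, alpha, kmax, nreal};
  double c1 = 0.0, c2 = 0.0;
  double grad[3], hess[9];
  auto eval = [&](double x, double y, double z) {
    double r[3] = {x, y, z};
    double rm[3] = {min_image(x, L), min_image(y, L), min_image(z, L)};
    double rr = std::sqrt(rm[0] * rm[0] + rm[1] * rm[1] + rm[2] * rm[2]);
    if (rr < rmin) return;
    ewald_kernel_derivs(r, ew, grad, hess);
    double r2 = rr * rr, r3 = r2 * rr, r5 = r3 * r2;
    double dg = 0.0, dh = 0.0;
    for (int i = 0; i < 3; ++i) {
      double gb = -rm[i] / r3;  // grad of 1/r
      dg += (grad[i] - gb) * (grad[i] - gb);
      for (int j = 0; j < 3; ++j) {
        double hb = 3.0 * rm[i] * rm[j] / r5 - ((i == j) ? 1.0 / r3 : 0.0);
        double dd = hess[3 * j + i] - hb;
        dh += dd * dd;
      }
    }
    if (std::sqrt(dg) > c1) c1 = std::sqrt(dg);
    if (std::sqrt(dh) > c2) c2 = std::sqrt(dh);
  };
  for (int ix = 0; ix < ngrid; ++ix)
    for (int iy = 0; iy < ngrid; ++iy)
      for (int iz = 0; iz < ngrid; ++iz)
        eval((ix + 0.5) * L / ngrid - L / 2, (iy + 0.5) * L / ngrid - L / 2,
             (iz + 0.5) * L / ngrid - L / 2);
  for (int i = 0; i < nrandom; ++i)
    eval(L * (unif_rand() - 0.5), L * (unif_rand() - 0.5),
         L * (unif_rand() - 0.5));
  return List::create(_["grad_rest"] = margin * c1,
                      _["hess_rest"] = margin * c2);
}
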