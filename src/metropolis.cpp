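#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Reversible single-atom Metropolis sampler for SPC/Fw water.
//
// Each trial displaces one uniformly chosen atom inside a cube of per-species
// half-width and accepts with min(1, exp(-beta dU)). dU is computed from the
// affected factors only (bonds/bend of the molecule, LJ against other
// oxygens, molecular Coulomb against all other molecules). The reciprocal
// Ewald part uses an incrementally maintained total structure factor, which
// by the factor partition equals the sum over molecular pair factors exactly.
// The proposal half-widths are adapted per species toward a target
// acceptance rate during a burn-in phase and frozen afterwards.
// ---------------------------------------------------------------------------

namespace {

typedef std::complex<double> cplx;

struct Met {
  int N, Na;
  std::vector<double> pos, q;
  double L, beta;
  Spcfw ff;
  EwaldPars ew;
  const KTable* kt;
  std::vector<cplx> Stot;

  void rebuild_S() {
    const KTable& t = *kt;
    Stot.assign(t.kx.size(), cplx(0, 0));
    for (int i = 0; i < Na; ++i) {
      const double* r = &pos[3 * i];
      for (size_t k = 0; k < t.kx.size(); ++k) {
        double kr = t.kx[k] * r[0] + t.ky[k] * r[1] + t.kz[k] * r[2];
        Stot[k] += q[i] * cplx(std::cos(kr), std::sin(kr));
      }
    }
  }
};

// dU for moving atom i from xold to xnew
double delta_U(Met& M, int i, const double* xold, const double* xnew,
               std::vector<cplx>& delta /* out, sized K */) {
  int m = i / 3;
  double dU = 0.0;

  // intramolecular factors of molecule m
  double keep[3];
  std::copy(xold, xold + 3, keep);
  const double* xo = &M.pos[9 * m];
  const double* xh1 = &M.pos[9 * m + 3];
  const double* xh2 = &M.pos[9 * m + 6];
  auto intra = [&]() {
    double e = bend_energy_grad(xo, xh1, xh2, M.ff, nullptr, nullptr, nullptr);
    e += bond_energy_grad(xo, xh1, M.ff, nullptr);
    e += bond_energy_grad(xo, xh2, M.ff, nullptr);
    return e;
  };
  double e0 = intra();
  std::copy(xnew, xnew + 3, &M.pos[3 * i]);
  double e1 = intra();
  std::copy(keep, keep + 3, &M.pos[3 * i]);
  dU += e1 - e0;

  // Lennard-Jones between oxygens (minimum image)
  if (i % 3 == 0) {
    for (int mm = 0; mm < M.N; ++mm) {
      if (mm == m) continue;
      dU += lj_energy_grad(xnew, &M.pos[9 * mm], M.L, M.ff, nullptr) -
            lj_energy_grad(xold, &M.pos[9 * mm], M.L, M.ff, nullptr);
    }
  }

  // Coulomb, real-space part: atom i against atoms of other molecules
  double qi = M.q[i];
  for (int j = 0; j < M.Na; ++j) {
    if (j / 3 == m) continue;
    const double* xj = &M.pos[3 * j];
    for (int nx = -M.ew.nreal; nx <= M.ew.nreal; ++nx)
      for (int ny = -M.ew.nreal; ny <= M.ew.nreal; ++ny)
        for (int nz = -M.ew.nreal; nz <= M.ew.nreal; ++nz) {
          double rn[3], ro[3];
          for (int k = 0; k < 3; ++k) {
            double sh = (k == 0 ? nx : (k == 1 ? ny : nz)) * M.L;
            rn[k] = min_image(xnew[k] - xj[k], M.L) + sh;
            ro[k] = min_image(xold[k] - xj[k], M.L) + sh;
          }
          double r1 = std::sqrt(rn[0] * rn[0] + rn[1] * rn[1] + rn[2] * rn[2]);
          double r0 = std::sqrt(ro[0] * ro[0] + ro[1] * ro[1] + ro[2] * ro[2]);
          dU += M.ff.kc * qi * M.q[j] *
                (std::erfc(M.ew.alpha * r1) / r1 - std::erfc(M.ew.alpha * r0) / r0);
        }
  }

  // Coulomb, reciprocal part: 2 coef Re[delta conj(Stot - Smol)], with
  // Smol the structure factor of the moved atom's own molecule (its
  // intramolecular Coulomb is not part of the model)
  const KTable& t = *M.kt;
  const int kmax = M.ew.kmax;
  const int W = 2 * kmax + 1;
  static thread_local std::vector<double> pw;
  pw.assign(4 * 3 * 2 * (size_t)W, 0.0);
  // phase tables for: new position, old position, the two other atoms
  phase_powers(xnew, M.L, kmax, &pw[0]);
  phase_powers(xold, M.L, kmax, &pw[3 * 2 * (size_t)W]);
  int others[2], no = 0;
  for (int a = 0; a < 3; ++a)
    if (3 * m + a != i) others[no++] = 3 * m + a;
  phase_powers(&M.pos[3 * others[0]], M.L, kmax, &pw[2 * 3 * 2 * (size_t)W]);
  phase_powers(&M.pos[3 * others[1]], M.L, kmax, &pw[3 * 3 * 2 * (size_t)W]);
  double qo0 = M.q[others[0]], qo1 = M.q[others[1]];

  double drec = 0.0;
  for (size_t k = 0; k < t.kx.size(); ++k) {
    const int ox = 2 * (kmax + t.mx[k]);
    const int oy = 2 * W + 2 * (kmax + t.my[k]);
    const int oz = 4 * W + 2 * (kmax + t.mz[k]);
    double pr[4], pi[4];
    for (int j = 0; j < 4; ++j) {
      const double* p = &pw[(size_t)j * 3 * 2 * W];
      double tr = p[ox] * p[oy] - p[ox + 1] * p[oy + 1];
      double ti = p[ox] * p[oy + 1] + p[ox + 1] * p[oy];
      pr[j] = tr * p[oz] - ti * p[oz + 1];
      pi[j] = tr * p[oz + 1] + ti * p[oz];
    }
    double dr = qi * (pr[0] - pr[1]), di = qi * (pi[0] - pi[1]);
    delta[k] = cplx(dr, di);
    double Sr = M.Stot[k].real() -
                (qi * pr[1] + qo0 * pr[2] + qo1 * pr[3]);
    double Si = M.Stot[k].imag() -
                (qi * pi[1] + qo0 * pi[2] + qo1 * pi[3]);
    drec += 2.0 * t.coef[k] * (dr * Sr + di * Si);
  }
  dU += M.ff.kc * drec;
  return dU;
}

void polarization(const Met& M, double* P) {
  P[0] = P[1] = P[2] = 0;
  for (int m = 0; m < M.N; ++m) {
    const double* xo = &M.pos[9 * m];
    for (int k = 0; k < 3; ++k) P[k] += M.q[3 * m] * xo[k];
    for (int h = 1; h <= 2; ++h) {
      const double* xh = &M.pos[9 * m + 3 * h];
      for (int k = 0; k < 3; ++k)
        P[k] += M.q[3 * m + h] * (xo[k] + min_image(xh[k] - xo[k], M.L));
    }
  }
}

}  // namespace

// test hook: energy difference for moving one atom, as used by the
// Metropolis acceptance decision
// [[Rcpp::export(name = ".metropolis_delta_cpp")]]
double metropolis_delta_cpp(NumericMatrix positions, NumericVector charges,
                            double L, List ffpars, List ewald, int atom,
                            NumericVector xnew) {
  Met M;
  M.Na = positions.ncol();
  M.N = M.Na / 3;
  M.pos.assign(positions.begin(), positions.end());
  M.q.assign(charges.begin(), charges.end());
  M.L = L;
  M.beta = 1.0;
  M.ff = spcfw_from_list(ffpars);
  M.ew = EwaldPars{L, as<double>(ewald["alpha"]), as<int>(ewald["kmax"]),
                   as<int>(ewald["nreal"])};
  M.kt = &ktable_get(L, M.ew.alpha, M.ew.kmax);
  M.rebuild_S();
  std::vector<cplx> delta(M.kt->kx.size());
  double xold[3];
  std::copy(&M.pos[3 * (atom - 1)], &M.pos[3 * (atom - 1)] + 3, xold);
  double xn[3] = {xnew[0], xnew[1], xnew[2]};
  return delta_U(M, atom - 1, xold, xn, delta);
}

// [[Rcpp::export(name = ".run_metropolis_cpp")]]
List run_metropolis_cpp(NumericMatrix positions, NumericVector charges,
                        double L, double beta, List ffpars, List ewald,
                        List control) {
  Met M;
  M.Na = positions.ncol();
  M.N = M.Na / 3;
  M.pos.assign(positions.begin(), positions.end());
  M.q.assign(charges.begin(), charges.end());
  M.L = L;
  M.beta = beta;
  M.ff = spcfw_from_list(ffpars);
  M.ew = EwaldPars{L, as<double>(ewald["alpha"]), as<int>(ewald["kmax"]),
                   as<int>(ewald["nreal"])};
  M.kt = &ktable_get(L, M.ew.alpha, M.ew.kmax);
  M.rebuild_S();

  double dH = as<double>(control["delta_H"]);
  double dO = as<double>(control["delta_O"]);
  bool adapt = as<bool>(control["adapt"]);
  int n_batches = as<int>(control["n_adapt_batches"]);
  int batch = as<int>(control["batch_size"]);
  double target = as<double>(control["target_acceptance"]);
  long n_prod = as<double>(control["n_production"]);
  int sample_every = as<int>(control["sample_every"]);

  std::vector<cplx> delta(M.kt->kx.size());
  std::vector<double> histH, histO, accH_hist, accO_hist;
  long refresh = 0;

  auto one_trial = [&](double deltaH, double deltaO, bool& isH) {
    int i = (int)std::floor(unif_rand() * M.Na);
    if (i >= M.Na) i = M.Na - 1;
    isH = (i % 3 != 0);
    double del = isH ? deltaH : deltaO;
    double xold[3], xnew[3];
    std::copy(&M.pos[3 * i], &M.pos[3 * i] + 3, xold);
    for (int k = 0; k < 3; ++k)
      xnew[k] = xold[k] + del * (2.0 * unif_rand() - 1.0);
    double dU = delta_U(M, i, xold, xnew, delta);
    bool acc = (dU <= 0.0) || (unif_rand() < std::exp(-M.beta * dU));
    if (acc) {
      std::copy(xnew, xnew + 3, &M.pos[3 * i]);
      for (size_t k = 0; k < delta.size(); ++k) M.Stot[k] += delta[k];
      if (++refresh % 200000 == 0) M.rebuild_S();
    }
    return acc;
  };

  // adaptation phase (burn-in): multiplicative per-species update
  if (adapt) {
    for (int b = 0; b < n_batches; ++b) {
      long nH = 0, nO = 0, aH = 0, aO = 0;
      for (int t = 0; t < batch; ++t) {
        bool isH;
        bool acc = one_trial(dH, dO, isH);
        if (isH) { nH++; aH += acc; } else { nO++; aO += acc; }
      }
      double rH = nH ? (double)aH / nH : target;
      double rO = nO ? (double)aO / nO : target;
      dH *= std::sqrt(std::max(rH, 0.02) / target);
      dO *= std::sqrt(std::max(rO, 0.02) / target);
      dH = std::min(std::max(dH, 1e-4), L / 2);
      dO = std::min(std::max(dO, 1e-4), L / 2);
      histH.push_back(dH);
      histO.push_back(dO);
      accH_hist.push_back(rH);
      accO_hist.push_back(rO);
      Rcpp::checkUserInterrupt();
    }
    // freeze at the geometric mean of the last few batches to damp noise
    int tail = std::min<int>(5, histH.size());
    double gH = 0, gO = 0;
    for (int b = (int)histH.size() - tail; b < (int)histH.size(); ++b) {
      gH += std::log(histH[b]);
      gO += std::log(histO[b]);
    }
    dH = std::exp(gH / tail);
    dO = std::exp(gO / tail);
  }

  // production phase: frozen half-widths, strictly reversible chain
  long acc_all = 0, accH = 0, accO = 0, nH = 0, nO = 0;
  std::vector<double> stamps, Pser;
  for (long t = 0; t < n_prod; ++t) {
    bool isH;
    bool acc = one_trial(dH, dO, isH);
    acc_all += acc;
    if (isH) { nH++; accH += acc; } else { nO++; accO += acc; }
    if (sample_every > 0 && (t + 1) % sample_every == 0) {
      double P[3];
      polarization(M, P);
      stamps.push_back((double)(t + 1));
      Pser.insert(Pser.end(), P, P + 3);
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finalpos(3, M.Na);
  std::copy(M.pos.begin(), M.pos.end(), finalpos.begin());
  int ns = (int)stamps.size();
  NumericMatrix P(ns, 3);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) P(i, k) = Pser[3 * i + k];

  return List::create(
      _["final_positions"] = finalpos, _["stamps"] = stamps,
      _["polarization"] = P,
      _["acceptance"] = n_prod > 0 ? (double)acc_all / n_prod : NA_REAL,
      _["acceptance_H"] = nH > 0 ? (double)accH / nH : NA_REAL,
      _["acceptance_O"] = nO > 0 ? (double)accO / nO : NA_REAL,
      _["delta_H"] = dH, _["delta_O"] = dO,
      _["delta_H_history"] = histH, _["delta_O_history"] = histO,
      _["acceptance_H_history"] = accH_hist,
      _["acceptance_O_history"] = accO_hist);
}
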