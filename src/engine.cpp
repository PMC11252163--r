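#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Event-chain Monte Carlo engine for SPC/Fw water.
//
// Piecewise-deterministic Markov process: a single active atom moves on a
// straight line; harmonic-bond factors generate exact candidate event times,
// all other factors generate candidates from analytic envelope (bounding)
// rates followed by Poisson thinning. Long-range Coulomb and Lennard-Jones
// factors are optionally bundled by the cell-veto algorithm with Walker
// alias tables precomputed per Fibonacci velocity direction.
// ---------------------------------------------------------------------------

namespace {

constexpr double INF = std::numeric_limits<double>::infinity();

enum CandType {
  CAND_NONE = 0, CAND_BOND, CAND_BEND, CAND_COUL_DIRECT, CAND_LJ_DIRECT,
  CAND_COUL_CV, CAND_LJ_CV, CAND_SAMPLE, CAND_RESAMPLE, CAND_BOUNDARY,
  CAND_END
};

struct Engine {
  // system
  int N = 0, Na = 0;
  std::vector<double> pos;  // 3*Na, unwrapped per molecule
  std::vector<double> q;
  double L = 0, beta = 0;
  Spcfw ff;
  EwaldPars ew;

  // lifted state
  int variant = 0;  // 0 = newtonian, 1 = straight
  std::vector<double> vel;  // 3*Na (newtonian); straight uses entry of active
  int active = 0;
  double Ekin2 = 0;  // v^T v target (identity masses)
  double clock = 0;

  // run parameters
  double tau_chain = 0, sample_int = 0, duration = 0;
  double slice = 0.1;
  bool strict = true;
  bool store_configs = false;

  // envelope constants
  double c1_rest = 0;     // residual charge-field bound (per unit charge)
  double c2_rest = 0;     // residual field-gradient (Hessian) bound
  double m1_mol = 1.2;    // sum of |q_j| |delta_j| over one molecule (e A)
  double rho_mol = 1.3;   // max atom distance from barycenter (padded)
  double q_abs = 1.64;    // sum of |charges| in one molecule
  int axis_cycle = 0;

  // cell-veto
  bool cv = false;
  int nc = 0, excl = 2, D = 0, n_off = 0;
  double cell = 0;
  std::vector<int> off;            // 3*n_off
  std::vector<double> fib;         // 3*D
  std::vector<double> bC, bLJ;     // n_off x D, unit speed & unit charge
  std::vector<double> QC, QLJ;     // per-fib totals
  std::vector<double> cutC, cutLJ; // alias tables, n_off x D
  std::vector<int> idxC, idxLJ;
  std::vector<int> cellMolC, cellMolLJ;  // molecule -> cell (-1 surplus)
  std::vector<int> occC, occLJ;          // cell -> molecule (-1 empty)
  std::vector<int> surC, surLJ;          // surplus molecule lists

  // diagnostics
  double n_ev_bond = 0, n_ev_bend = 0, n_ev_lj = 0, n_ev_coul = 0;
  double n_cand_bend = 0, n_cand_lj = 0, n_cand_coul = 0;
  double n_cv_cand = 0, n_cv_empty = 0, n_violation = 0;
  int max_handlers = 0;
  double speed_time = 0, time_tot = 0;
  std::vector<double> stamps;
  std::vector<double> Pout;      // 3 per stamp
  std::vector<double> configs;   // optional 3*Na per stamp

  double sp() const {
    const double* v = &vel[3 * active];
    return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  }
  int molOf(int atom) const { return atom / 3; }
  void barycenter(int m, double* b) const {
    for (int k = 0; k < 3; ++k)
      b[k] = (pos[9 * m + k] + pos[9 * m + 3 + k] + pos[9 * m + 6 + k]) / 3.0;
  }
  int binPoint(const double* p) const {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double x = p[k] - L * std::floor(p[k] / L);
      int i = (int)std::floor(x / cell);
      if (i >= nc) i = nc - 1;
      if (i < 0) i = 0;
      c[k] = i;
    }
    return (c[2] * nc + c[1]) * nc + c[0];
  }
  void cellCoords(int cidx, int* c) const {
    c[0] = cidx % nc; c[1] = (cidx / nc) % nc; c[2] = cidx / (nc * nc);
  }
};

// --- occupancy -------------------------------------------------------------

void occ_remove(std::vector<int>& cellMol, std::vector<int>& occ,
                std::vector<int>& sur, int m) {
  int c = cellMol[m];
  if (c >= 0) {
    occ[c] = -1;
  } else {
    for (size_t i = 0; i < sur.size(); ++i)
      if (sur[i] == m) { sur[i] = sur.back(); sur.pop_back(); break; }
  }
  cellMol[m] = -2;
}

void occ_insert(std::vector<int>& cellMol, std::vector<int>& occ,
                std::vector<int>& sur, int m, int c) {
  if (occ[c] < 0) {
    occ[c] = m;
    cellMol[m] = c;
  } else {
    sur.push_back(m);
    cellMol[m] = -1;
  }
}

// re-bin molecule m; vacated cells may promote a surplus molecule
void rebin(Engine& E, int m, bool lj_system) {
  std::vector<int>& cellMol = lj_system ? E.cellMolLJ : E.cellMolC;
  std::vector<int>& occ = lj_system ? E.occLJ : E.occC;
  std::vector<int>& sur = lj_system ? E.surLJ : E.surC;
  double p[3];
  if (lj_system) {
    p[0] = E.pos[9 * m]; p[1] = E.pos[9 * m + 1]; p[2] = E.pos[9 * m + 2];
  } else {
    E.barycenter(m, p);
  }
  int cnew = E.binPoint(p);
  int cold = cellMol[m];
  if (cold == cnew) return;
  occ_remove(cellMol, occ, sur, m);
  occ_insert(cellMol, occ, sur, m, cnew);
  if (cold >= 0 && occ[cold] < 0) {
    // promote a surplus molecule that actually sits in the vacated cell
    for (size_t i = 0; i < sur.size(); ++i) {
      int s = sur[i];
      double ps[3];
      if (lj_system) {
        ps[0] = E.pos[9 * s]; ps[1] = E.pos[9 * s + 1]; ps[2] = E.pos[9 * s + 2];
      } else {
        E.barycenter(s, ps);
      }
      if (E.binPoint(ps) == cold) {
        sur[i] = sur.back(); sur.pop_back();
        occ[cold] = s;
        cellMol[s] = cold;
        break;
      }
    }
  }
}

void occ_init(Engine& E) {
  E.cellMolC.assign(E.N, -2);
  E.cellMolLJ.assign(E.N, -2);
  E.occC.assign(E.nc * E.nc * E.nc, -1);
  E.occLJ.assign(E.nc * E.nc * E.nc, -1);
  E.surC.clear(); E.surLJ.clear();
  for (int m = 0; m < E.N; ++m) {
    double b[3];
    E.barycenter(m, b);
    occ_insert(E.cellMolC, E.occC, E.surC, m, E.binPoint(b));
    occ_insert(E.cellMolLJ, E.occLJ, E.surLJ, m, E.binPoint(&E.pos[9 * m]));
  }
}

// --- geometry helpers ------------------------------------------------------

double dist_mi(const Engine& E, const double* a, const double* b) {
  double s = 0;
  for (int k = 0; k < 3; ++k) {
    double d = min_image(a[k] - b[k], E.L);
    s += d * d;
  }
  return std::sqrt(s);
}

int nearest_fib_idx(const Engine& E, const double* v) {
  double best = -2.0;
  int bi = 0;
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  for (int d = 0; d < E.D; ++d) {
    double dot = (v[0] * E.fib[3 * d] + v[1] * E.fib[3 * d + 1] +
                  v[2] * E.fib[3 * d + 2]) / n;
    if (dot > best) { best = dot; bi = d; }
  }
  return bi;
}

// --- exact harmonic-bond event time ----------------------------------------

// Candidate event time for a harmonic bond factor under straight motion of
// the active atom: the uphill potential increments are integrated in closed
// form piecewise between monotonicity breakpoints and inverted.
double bond_candidate_thr(const double* xi, const double* xj, const double* v,
                          double beta, const Spcfw& ff, double Tend,
                          double E_thr) {
  double c0[3] = {xi[0] - xj[0], xi[1] - xj[1], xi[2] - xj[2]};
  double A = c0[0] * c0[0] + c0[1] * c0[1] + c0[2] * c0[2];
  double a = c0[0] * v[0] + c0[1] * v[1] + c0[2] * v[2];
  double s2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  double s = std::sqrt(s2);
  double tstar = -a / s2;
  double rmin2 = A - a * a / s2;
  if (rmin2 < 0) rmin2 = 0;
  double rmin = std::sqrt(rmin2);
  const double l0 = ff.l0, kb = ff.kb;

  double bps[4];
  int nb = 0;
  bps[nb++] = 0.0;
  double tc1 = INF, tc2 = INF;
  if (rmin < l0) {
    double w = std::sqrt(l0 * l0 - rmin2) / s;
    tc1 = tstar - w;
    tc2 = tstar + w;
  }
  if (tc1 > 0 && tc1 < INF) bps[nb++] = tc1;
  if (tstar > 0) bps[nb++] = tstar;
  if (tc2 > 0 && tc2 < INF) bps[nb++] = tc2;
  std::sort(bps, bps + nb);

  double E = E_thr;
  auto r_at = [&](double t) {
    double r2 = A + 2 * a * t + s2 * t * t;
    return r2 > 0 ? std::sqrt(r2) : 0.0;
  };
  auto u_of = [&](double r) { double d = r - l0; return 0.5 * kb * d * d; };

  for (int seg = 0; seg < nb; ++seg) {
    double ts = bps[seg];
    double te = (seg + 1 < nb) ? bps[seg + 1] : INF;
    double rs = r_at(ts);
    double re = (te == INF) ? INF : r_at(te);
    double us = u_of(rs);
    double ue = (te == INF) ? INF : u_of(re);
    if (ue <= us) continue;  // downhill or flat: no integrated rate
    double cap = beta * (ue - us);
    if (E > cap) { E -= cap; continue; }
    double ut = us + E / beta;
    double dd = std::sqrt(2.0 * ut / kb);
    bool increasing = (te == INF) ? true : (re > rs);
    double rt = increasing ? (l0 + dd) : (l0 - dd);
    // uphill decreasing segments live below l0; uphill increasing above
    if (increasing && rs < l0) rt = l0 + dd;  // starts at l0 crossing
    double disc = rt * rt - rmin2;
    if (disc < 0) disc = 0;
    double t = increasing ? (tstar + std::sqrt(disc) / s)
                          : (tstar - std::sqrt(disc) / s);
    if (t < ts) t = ts;
    if (t > Tend) return INF;
    return t;
  }
  return INF;
}

double bond_candidate(const double* xi, const double* xj, const double* v,
                      double beta, const Spcfw& ff, double Tend,
                      double* bound_out) {
  if (bound_out) *bound_out = -1.0;  // exact solver: no thinning bound
  return bond_candidate_thr(xi, xj, v, beta, ff, Tend, exp_rand());
}

// --- envelope (bounding-rate) candidate generators -------------------------

// first arrival of a piecewise-constant bounding-rate Poisson process; the
// per-slice bound comes from a closed-form envelope of the factor event rate
template <typename BoundFn>
double envelope_candidate(double Tend, double slice_t, BoundFn bound,
                          double* bound_out) {
  double t = 0.0;
  while (t < Tend) {
    double tb = std::min(t + slice_t, Tend);
    double lam = bound(t, tb);
    if (lam > 0) {
      double e = exp_rand();
      double ta = t + e / lam;
      if (ta <= tb) {
        *bound_out = lam;
        return ta;
      }
    }
    t = tb;
  }
  return INF;
}

// bend factor: |grad_theta| <= 1/r1 + 1/r2 bounds both dtheta/dt and the
// change of theta across a slice
double bend_envelope_candidate(const Engine& E, double Tend, double* bound_out) {
  int m = E.molOf(E.active);
  const double* xo = &E.pos[9 * m];
  const double* xh1 = &E.pos[9 * m + 3];
  const double* xh2 = &E.pos[9 * m + 6];
  double s = E.sp();
  double slice_t = E.slice / s;
  return envelope_candidate(Tend, slice_t, [&](double ta, double tb) {
    double ds_done = ta * s, ds_len = (tb - ta) * s;
    // current deviation |theta - theta0| at ta (advance active temporarily)
    double p[9];
    std::copy(xo, xo + 3, p);
    std::copy(xh1, xh1 + 3, p + 3);
    std::copy(xh2, xh2 + 3, p + 6);
    int li = E.active - 3 * m;
    for (int k = 0; k < 3; ++k) p[3 * li + k] += E.vel[3 * E.active + k] * ta;
    double u[3] = {p[3] - p[0], p[4] - p[1], p[5] - p[2]};
    double w[3] = {p[6] - p[0], p[7] - p[1], p[8] - p[2]};
    double r1 = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double r2 = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    double c = (u[0] * w[0] + u[1] * w[1] + u[2] * w[2]) / (r1 * r2);
    if (c > 1) c = 1;
    if (c < -1) c = -1;
    double dev = std::fabs(std::acos(c) - E.ff.th0);
    double r1m = std::max(r1 - ds_len, 0.3), r2m = std::max(r2 - ds_len, 0.3);
    double kappa = 1.0 / r1m + 1.0 / r2m;
    (void)ds_done;
    return E.beta * E.ff.ka * (dev + ds_len * kappa) * s * kappa;
  }, bound_out);
}

// direct molecular-Coulomb factor. Two rigorous envelopes of the periodic
// field of a neutral molecule at the active charge, combined by min():
//   monopole magnitude: sum_j |q_j| (1/d^2 + C1), valid at any distance;
//   neutrality-aware:   sum_j |q_j||delta_j| (2/d^3 + C2) by the mean-value
//     theorem on grad psi_E between the barycenter and the atom sites,
//     much tighter at long range.
double coul_envelope_candidate(const Engine& E, int mtarget, double Tend,
                               double* bound_out) {
  double b[3];
  E.barycenter(mtarget, b);
  const double* xa0 = &E.pos[3 * E.active];
  double d0 = dist_mi(E, xa0, b);
  const double* v = &E.vel[3 * E.active];
  double s = E.sp();
  double qa = std::fabs(E.q[E.active]);
  double slice_t = E.slice / s;
  // per-target-atom geometry at the slice start (hoisted: targets are
  // static, the active atom advances)
  return envelope_candidate(Tend, slice_t, [&](double ta, double tb) {
    // far-field: neutrality-aware first-moment bound at the barycenter
    double db = std::max(d0 - tb * s - E.rho_mol, 0.5);
    double dip = E.m1_mol * (2.0 / (db * db * db) + E.c2_rest);
    // near-field: per charge pair with directional clamp; c_j = cosine of
    // the angle between the motion and the pair axis, drifting by at most
    // travel/d across the slice
    double mono = 0.0;
    double travel = (tb - ta) * s;
    for (int j = 0; j < 3; ++j) {
      const double* xj = &E.pos[9 * mtarget + 3 * j];
      double r[3], d2 = 0;
      for (int k = 0; k < 3; ++k) {
        r[k] = min_image(xj[k] - (xa0[k] + v[k] * ta), E.L);
        d2 += r[k] * r[k];
      }
      double d = std::sqrt(d2);
      double de = std::max(d - travel, 0.4);
      double c = (r[0] * v[0] + r[1] * v[1] + r[2] * v[2]) / (d * s);
      double sgn = (E.q[E.active] * E.q[3 * mtarget + j] > 0) ? 1.0 : -1.0;
      double ce = std::min(1.0, sgn * c + travel / de);
      if (ce > 0) mono += std::fabs(E.q[3 * mtarget + j]) * ce / (de * de);
    }
    mono += E.q_abs * E.c1_rest;
    return E.beta * qa * s * E.ff.kc * std::min(mono, dip);
  }, bound_out);
}

// direct Lennard-Jones factor (two oxygens, minimum image): interval maximum
// of |U'| over the reachable separations in the slice
double lj_envelope_candidate(const Engine& E, int mtarget, double Tend,
                             double* bound_out) {
  double d0 = dist_mi(E, &E.pos[3 * E.active], &E.pos[9 * mtarget]);
  double s = E.sp();
  double slice_t = E.slice / s;
  const Spcfw& ff = E.ff;
  double r_infl = std::pow(26.0 / 7.0, 1.0 / 6.0) * ff.sigma;
  return envelope_candidate(Tend, slice_t, [&](double ta, double tb) {
    double lo = std::max(d0 - tb * s, 0.5);
    double hi = d0 + tb * s;
    double m = std::max(lj_abs_dudr(lo, ff), lj_abs_dudr(hi, ff));
    if (r_infl > lo && r_infl < hi) m = std::max(m, lj_abs_dudr(r_infl, ff));
    return E.beta * s * m;
  }, bound_out);
}

// --- factor gradients at event time ----------------------------------------

// computes gradients of the event factor on its atoms; returns rate on the
// active atom (beta max(0, g_i . v_i))
double coul_factor_grads(Engine& E, int m1, int m2, double* g1, double* g2) {
  std::fill(g1, g1 + 9, 0.0);
  std::fill(g2, g2 + 9, 0.0);
  ewald_group_pair(&E.pos[9 * m1], &E.q[3 * m1], 3, &E.pos[9 * m2],
                   &E.q[3 * m2], 3, E.ew, E.ff.kc, g1, g2);
  return 0.0;
}

// --- lifting schemes -------------------------------------------------------

// Newtonian-pair: deterministic force kick on both atoms (identity masses),
// activity transferred to the other atom
void lift_pair_apply(Engine& E, int a, int b, const double* ga) {
  double* va = &E.vel[3 * a];
  double* vb = &E.vel[3 * b];
  double g2 = ga[0] * ga[0] + ga[1] * ga[1] + ga[2] * ga[2];
  double num = (va[0] - vb[0]) * ga[0] + (va[1] - vb[1]) * ga[1] +
               (va[2] - vb[2]) * ga[2];
  double f = num / g2;
  for (int k = 0; k < 3; ++k) {
    va[k] -= f * ga[k];
    vb[k] += f * ga[k];
  }
  E.active = (E.active == a) ? b : a;
}

// Newtonian-general: stochastic choice among (k, v') and (k, v)
void lift_general_apply(Engine& E, const int* atoms, const double* grads,
                        int nat) {
  double phi_num = 0, phi_den = 0;
  for (int j = 0; j < nat; ++j) {
    const double* vj = &E.vel[3 * atoms[j]];
    const double* gj = grads + 3 * j;
    phi_num += vj[0] * gj[0] + vj[1] * gj[1] + vj[2] * gj[2];
    phi_den += gj[0] * gj[0] + gj[1] * gj[1] + gj[2] * gj[2];
  }
  double phi = 2.0 * phi_num / phi_den;
  // outcome weights: kick branch then keep branch, per contributing atom
  double w[24];
  double C = 0;
  for (int j = 0; j < nat; ++j) {
    const double* vj = &E.vel[3 * atoms[j]];
    const double* gj = grads + 3 * j;
    double gv = vj[0] * gj[0] + vj[1] * gj[1] + vj[2] * gj[2];
    double gg = gj[0] * gj[0] + gj[1] * gj[1] + gj[2] * gj[2];
    double gvp = gv - phi * gg;  // g_j . v'_j
    w[2 * j] = std::max(0.0, -gvp);
    w[2 * j + 1] = std::max(0.0, -gv);
    C += w[2 * j] + w[2 * j + 1];
  }
  double u = unif_rand() * C;
  int pick = 2 * nat - 1;
  for (int i = 0; i < 2 * nat; ++i) {
    u -= w[i];
    if (u <= 0) { pick = i; break; }
  }
  int k = atoms[pick / 2];
  if (pick % 2 == 0) {
    for (int j = 0; j < nat; ++j) {
      double* vj = &E.vel[3 * atoms[j]];
      const double* gj = grads + 3 * j;
      for (int d = 0; d < 3; ++d) vj[d] -= phi * gj[d];
    }
  }
  E.active = k;
}

// straight-variant ratio lifting: velocity transferred unchanged, target
// atom sampled with probability proportional to max(0, -grad_k . v)
void lift_straight_apply(Engine& E, const int* atoms, const double* grads,
                         int nat) {
  const double v[3] = {E.vel[3 * E.active], E.vel[3 * E.active + 1],
                       E.vel[3 * E.active + 2]};
  if (nat == 2) {
    int k = (atoms[0] == E.active) ? atoms[1] : atoms[0];
    for (int d = 0; d < 3; ++d) {
      E.vel[3 * k + d] = v[d];
      E.vel[3 * E.active + d] = 0.0;
    }
    E.active = k;
    return;
  }
  double w[8], C = 0;
  for (int j = 0; j < nat; ++j) {
    const double* gj = grads + 3 * j;
    w[j] = std::max(0.0, -(gj[0] * v[0] + gj[1] * v[1] + gj[2] * v[2]));
    C += w[j];
  }
  double u = unif_rand() * C;
  int pick = nat - 1;
  for (int j = 0; j < nat; ++j) {
    u -= w[j];
    if (u <= 0) { pick = j; break; }
  }
  int k = atoms[pick];
  for (int d = 0; d < 3; ++d) {
    E.vel[3 * E.active + d] = 0.0;
    E.vel[3 * k + d] = v[d];
  }
  E.active = k;
}

// --- resampling ------------------------------------------------------------

void resample(Engine& E) {
  if (E.variant == 1) {
    // straight: unit velocity cycling through the six axis directions
    static const double axes[6][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1},
                                      {-1, 0, 0}, {0, -1, 0}, {0, 0, -1}};
    std::fill(E.vel.begin(), E.vel.end(), 0.0);
    int a = (int)std::floor(unif_rand() * E.Na);
    if (a >= E.Na) a = E.Na - 1;
    E.active = a;
    const double* ax = axes[E.axis_cycle % 6];
    E.axis_cycle++;
    for (int k = 0; k < 3; ++k) E.vel[3 * a + k] = ax[k];
    return;
  }
  // newtonian: Gaussian draw, remove componentwise mean, rescale to fixed
  // kinetic energy, uniform active label
  double mean[3] = {0, 0, 0};
  for (int i = 0; i < E.Na; ++i)
    for (int k = 0; k < 3; ++k) {
      E.vel[3 * i + k] = norm_rand();
      mean[k] += E.vel[3 * i + k];
    }
  for (int k = 0; k < 3; ++k) mean[k] /= E.Na;
  double ss = 0;
  for (int i = 0; i < E.Na; ++i)
    for (int k = 0; k < 3; ++k) {
      E.vel[3 * i + k] -= mean[k];
      ss += E.vel[3 * i + k] * E.vel[3 * i + k];
    }
  double scale = std::sqrt(E.Ekin2 / ss);
  for (int i = 0; i < 3 * E.Na; ++i) E.vel[i] *= scale;
  int a = (int)std::floor(unif_rand() * E.Na);
  if (a >= E.Na) a = E.Na - 1;
  E.active = a;
}

// --- sampling --------------------------------------------------------------

void record_sample(Engine& E, double t) {
  double P[3] = {0, 0, 0};
  for (int m = 0; m < E.N; ++m) {
    const double* xo = &E.pos[9 * m];
    for (int h = 1; h <= 2; ++h) {
      const double* xh = &E.pos[9 * m + 3 * h];
      for (int k = 0; k < 3; ++k)
        P[k] += E.q[3 * m + h] * (xo[k] + min_image(xh[k] - xo[k], E.L));
    }
    for (int k = 0; k < 3; ++k) P[k] += E.q[3 * m] * xo[k];
  }
  E.stamps.push_back(t);
  for (int k = 0; k < 3; ++k) E.Pout.push_back(P[k]);
  if (E.store_configs)
    E.configs.insert(E.configs.end(), E.pos.begin(), E.pos.end());
}

// --- near lists ------------------------------------------------------------

void near_molecules(const Engine& E, bool lj_system, std::vector<int>& out) {
  out.clear();
  int am = E.active / 3;
  if (!E.cv) {
    for (int m = 0; m < E.N; ++m)
      if (m != am) out.push_back(m);
    return;
  }
  const std::vector<int>& occ = lj_system ? E.occLJ : E.occC;
  const std::vector<int>& sur = lj_system ? E.surLJ : E.surC;
  double p[3];
  if (lj_system) {
    p[0] = E.pos[3 * E.active]; p[1] = E.pos[3 * E.active + 1];
    p[2] = E.pos[3 * E.active + 2];
  } else {
    E.barycenter(am, p);
  }
  int c0 = E.binPoint(p);
  int cc[3];
  E.cellCoords(c0, cc);
  std::vector<char> seen(E.nc * E.nc * E.nc, 0);
  for (int dx = -E.excl; dx <= E.excl; ++dx)
    for (int dy = -E.excl; dy <= E.excl; ++dy)
      for (int dz = -E.excl; dz <= E.excl; ++dz) {
        int ix = ((cc[0] + dx) % E.nc + E.nc) % E.nc;
        int iy = ((cc[1] + dy) % E.nc + E.nc) % E.nc;
        int iz = ((cc[2] + dz) % E.nc + E.nc) % E.nc;
        int c = (iz * E.nc + iy) * E.nc + ix;
        if (seen[c]) continue;
        seen[c] = 1;
        int m = occ[c];
        if (m >= 0 && m != am) out.push_back(m);
      }
  for (int m : sur)
    if (m != am) out.push_back(m);
}

// --- boundary crossing -----------------------------------------------------

double boundary_time(const Engine& E, const double* p, const double* w) {
  double tmin = INF;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(w[k]) < 1e-14) continue;
    double x = p[k] - E.L * std::floor(p[k] / E.L);
    double y = x - E.cell * std::floor(x / E.cell);
    double dist = (w[k] > 0) ? (E.cell - y) : y;
    if (dist <= 1e-12) dist = E.cell;
    double t = dist / std::fabs(w[k]);
    if (t < tmin) tmin = t;
  }
  return tmin;
}

}  // namespace

// [[Rcpp::export(name = ".run_ecmc_cpp")]]
List run_ecmc_cpp(NumericMatrix positions, NumericVector charges, double L,
                  double beta, List ffpars, List ewald, List control,
                  Nullable<List> cellveto) {
  Engine E;
  E.Na = positions.ncol();
  E.N = E.Na / 3;
  if (E.Na % 3 != 0 || positions.nrow() != 3) stop("positions must be 3 x 3N");
  E.pos.assign(positions.begin(), positions.end());
  E.q.assign(charges.begin(), charges.end());
  E.L = L;
  E.beta = beta;
  E.ff = spcfw_from_list(ffpars);
  E.ew = EwaldPars{L, as<double>(ewald["alpha"]), as<int>(ewald["kmax"]),
                   as<int>(ewald["nreal"])};

  std::string var = as<std::string>(control["variant"]);
  E.variant = (var == "straight") ? 1 : 0;
  E.tau_chain = as<double>(control["tau_chain"]);
  E.sample_int = as<double>(control["sampling_interval"]);
  E.duration = as<double>(control["duration"]);
  E.slice = as<double>(control["slice_length"]);
  E.strict = as<bool>(control["strict"]);
  E.store_configs = as<bool>(control["store_configs"]);
  E.c1_rest = as<double>(control["c1_rest"]);
  E.c2_rest = as<double>(control["c2_rest"]);
  E.m1_mol = as<double>(control["m1_mol"]);
  E.rho_mol = as<double>(control["rho_mol"]);
  E.q_abs = 2.0 * std::fabs(E.ff.qH) + std::fabs(E.ff.qO);
  E.Ekin2 = 3.0 * E.Na * M_PI / 8.0;
  E.vel.assign(3 * E.Na, 0.0);

  if (cellveto.isNotNull()) {
    List cvl(cellveto);
    E.cv = true;
    E.nc = as<int>(cvl["n_cells"]);
    E.excl = as<int>(cvl["excluded_layers"]);
    E.cell = L / E.nc;
    IntegerMatrix offm = cvl["offsets"];  // n_off x 3
    E.n_off = offm.nrow();
    E.off.resize(3 * E.n_off);
    for (int i = 0; i < E.n_off; ++i)
      for (int k = 0; k < 3; ++k) E.off[3 * i + k] = offm(i, k);
    NumericMatrix fibm = cvl["fib_vectors"];  // D x 3
    E.D = fibm.nrow();
    E.fib.resize(3 * E.D);
    for (int d = 0; d < E.D; ++d)
      for (int k = 0; k < 3; ++k) E.fib[3 * d + k] = fibm(d, k);
    NumericMatrix bC = cvl["bounds_coulomb"], bLJ = cvl["bounds_lj"];
    NumericMatrix cutC = cvl["alias_cut_coulomb"], cutLJ = cvl["alias_cut_lj"];
    IntegerMatrix idxC = cvl["alias_index_coulomb"], idxLJ = cvl["alias_index_lj"];
    E.bC.assign(bC.begin(), bC.end());
    E.bLJ.assign(bLJ.begin(), bLJ.end());
    E.cutC.assign(cutC.begin(), cutC.end());
    E.cutLJ.assign(cutLJ.begin(), cutLJ.end());
    E.idxC.assign(idxC.begin(), idxC.end());
    E.idxLJ.assign(idxLJ.begin(), idxLJ.end());
    E.QC.assign(E.D, 0.0);
    E.QLJ.assign(E.D, 0.0);
    for (int d = 0; d < E.D; ++d)
      for (int o = 0; o < E.n_off; ++o) {
        E.QC[d] += E.bC[d * E.n_off + o];
        E.QLJ[d] += E.bLJ[d * E.n_off + o];
      }
    occ_init(E);
  }

  resample(E);
  double vtv0 = 0;
  for (double v : E.vel) vtv0 += v * v;

  record_sample(E, 0.0);
  long n_sampled = 0, n_resampled = 0;
  std::vector<int> nearC, nearLJ;
  double g1[9], g2[9];

  while (E.clock < E.duration - 1e-12) {
    double t0 = E.clock;
    double s = E.sp();
    bool activeO = (E.active % 3 == 0);
    int am = E.active / 3;

    // deterministic horizon
    double T_sample = (n_sampled + 1) * E.sample_int;
    double T_resample = (n_resampled + 1) * E.tau_chain;
    double Tend_abs = T_sample;
    int end_type = CAND_SAMPLE;  // ties resolve in favour of sampling
    if (T_resample < Tend_abs) { Tend_abs = T_resample; end_type = CAND_RESAMPLE; }
    if (E.duration < Tend_abs) { Tend_abs = E.duration; end_type = CAND_END; }

    double Tb = INF;
    if (E.cv) {
      double bmol[3], vb[3];
      E.barycenter(am, bmol);
      for (int k = 0; k < 3; ++k) vb[k] = E.vel[3 * E.active + k] / 3.0;
      Tb = boundary_time(E, bmol, vb);
      if (activeO) {
        double tO = boundary_time(E, &E.pos[3 * E.active], &E.vel[3 * E.active]);
        Tb = std::min(Tb, tO);
      }
    }
    if (t0 + Tb < Tend_abs) {
      Tend_abs = t0 + Tb;
      end_type = CAND_BOUNDARY;
    }
    double Tend = Tend_abs - t0;  // piece-local horizon

    // gather candidates
    double best_t = Tend;
    int best_type = end_type;
    int best_target = -1;
    double best_bound = 0;
    int handlers = 3;

    // bonds of the active atom
    for (int h = 1; h <= 2; ++h) {
      int iO = 3 * am, iH = 3 * am + h;
      if (E.active != iO && E.active != iH) continue;
      int other = (E.active == iO) ? iH : iO;
      double bb;
      double t = bond_candidate(&E.pos[3 * E.active], &E.pos[3 * other],
                                &E.vel[3 * E.active], E.beta, E.ff, best_t, &bb);
      handlers++;
      if (t < best_t) {
        best_t = t; best_type = CAND_BOND; best_target = other;
      }
    }
    // bend
    {
      double bb;
      double t = bend_envelope_candidate(E, best_t, &bb);
      if (t < best_t) {
        best_t = t; best_type = CAND_BEND; best_bound = bb;
      }
    }
    // direct Coulomb
    near_molecules(E, false, nearC);
    handlers += (int)nearC.size();
    for (int m : nearC) {
      double bb;
      double t = coul_envelope_candidate(E, m, best_t, &bb);
      if (t < best_t) {
        best_t = t; best_type = CAND_COUL_DIRECT; best_target = m;
        best_bound = bb;
      }
    }
    // direct LJ
    if (activeO) {
      near_molecules(E, true, nearLJ);
      handlers += (int)nearLJ.size();
      for (int m : nearLJ) {
        double bb;
        double t = lj_envelope_candidate(E, m, best_t, &bb);
        if (t < best_t) {
          best_t = t; best_type = CAND_LJ_DIRECT; best_target = m;
          best_bound = bb;
        }
      }
    }
    // cell veto
    int fibi = -1;
    if (E.cv) {
      fibi = nearest_fib_idx(E, &E.vel[3 * E.active]);
      handlers += 2;
      double Q = E.QC[fibi] * s * std::fabs(E.q[E.active]);
      if (Q > 0) {
        double t = exp_rand() / Q;
        if (t < best_t) { best_t = t; best_type = CAND_COUL_CV; }
      }
      if (activeO && E.QLJ[fibi] > 0) {
        double t = exp_rand() / (E.QLJ[fibi] * s);
        if (t < best_t) { best_t = t; best_type = CAND_LJ_CV; }
      }
    }
    if (handlers > E.max_handlers) E.max_handlers = handlers;

    // advance the active atom
    for (int k = 0; k < 3; ++k) E.pos[3 * E.active + k] += E.vel[3 * E.active + k] * best_t;
    E.clock = (best_type == CAND_SAMPLE || best_type == CAND_RESAMPLE ||
               best_type == CAND_END)
                  ? Tend_abs
                  : t0 + best_t;
    E.speed_time += s * best_t;
    E.time_tot += best_t;

    switch (best_type) {
      case CAND_SAMPLE:
        record_sample(E, E.clock);
        n_sampled++;
        break;
      case CAND_RESAMPLE:
        resample(E);
        n_resampled++;
        break;
      case CAND_END:
        break;
      case CAND_BOUNDARY:
        rebin(E, am, false);
        rebin(E, am, true);
        break;
      case CAND_BOND: {
        double ga[3];
        bond_energy_grad(&E.pos[3 * E.active], &E.pos[3 * best_target], E.ff, ga);
        E.n_ev_bond++;
        if (E.variant == 0) {
          lift_pair_apply(E, E.active, best_target, ga);
        } else {
          int atoms[2] = {E.active, best_target};
          double gr[6] = {ga[0], ga[1], ga[2], -ga[0], -ga[1], -ga[2]};
          lift_straight_apply(E, atoms, gr, 2);
        }
        break;
      }
      case CAND_BEND: {
        double gO[3], gH1[3], gH2[3];
        bend_energy_grad(&E.pos[9 * am], &E.pos[9 * am + 3], &E.pos[9 * am + 6],
                         E.ff, gO, gH1, gH2);
        const double* gact = (E.active == 3 * am) ? gO
                             : (E.active == 3 * am + 1) ? gH1 : gH2;
        const double* v = &E.vel[3 * E.active];
        double rate = E.beta * std::max(0.0, gact[0] * v[0] + gact[1] * v[1] +
                                                 gact[2] * v[2]);
        E.n_cand_bend++;
        if (rate > best_bound * (1 + 1e-9)) {
          E.n_violation++;
          if (E.strict) stop("bend bounding rate violated");
        }
        if (unif_rand() < rate / best_bound) {
          E.n_ev_bend++;
          int atoms[3] = {3 * am, 3 * am + 1, 3 * am + 2};
          double gr[9];
          std::copy(gO, gO + 3, gr);
          std::copy(gH1, gH1 + 3, gr + 3);
          std::copy(gH2, gH2 + 3, gr + 6);
          if (E.variant == 0)
            lift_general_apply(E, atoms, gr, 3);
          else
            lift_straight_apply(E, atoms, gr, 3);
        }
        break;
      }
      case CAND_LJ_DIRECT:
      case CAND_LJ_CV: {
        int mt = best_target;
        double bound = best_bound;
        if (best_type == CAND_LJ_CV) {
          E.n_cv_cand++;
          // sample target cell from the Walker table
          int o = (int)std::floor(unif_rand() * E.n_off);
          if (o >= E.n_off) o = E.n_off - 1;
          if (unif_rand() >= E.cutLJ[fibi * E.n_off + o])
            o = E.idxLJ[fibi * E.n_off + o];
          int cc[3];
          E.cellCoords(E.binPoint(&E.pos[3 * E.active]), cc);
          int ix = ((cc[0] + E.off[3 * o]) % E.nc + E.nc) % E.nc;
          int iy = ((cc[1] + E.off[3 * o + 1]) % E.nc + E.nc) % E.nc;
          int iz = ((cc[2] + E.off[3 * o + 2]) % E.nc + E.nc) % E.nc;
          mt = E.occLJ[(iz * E.nc + iy) * E.nc + ix];
          if (mt < 0 || mt == am) { E.n_cv_empty++; break; }
          bound = E.bLJ[fibi * E.n_off + o] * s;
        }
        double ga[3];
        lj_energy_grad(&E.pos[3 * E.active], &E.pos[9 * mt], E.L, E.ff, ga);
        const double* v = &E.vel[3 * E.active];
        double rate = E.beta * std::max(0.0, ga[0] * v[0] + ga[1] * v[1] +
                                                 ga[2] * v[2]);
        E.n_cand_lj++;
        if (rate > bound * (1 + 1e-9)) {
          E.n_violation++;
          if (E.strict) stop("LJ bounding rate violated");
        }
        if (unif_rand() < rate / bound) {
          E.n_ev_lj++;
          if (E.variant == 0) {
            lift_pair_apply(E, E.active, 3 * mt, ga);
          } else {
            int atoms[2] = {E.active, 3 * mt};
            double gr[6] = {ga[0], ga[1], ga[2], -ga[0], -ga[1], -ga[2]};
            lift_straight_apply(E, atoms, gr, 2);
          }
        }
        break;
      }
      case CAND_COUL_DIRECT:
      case CAND_COUL_CV: {
        int mt = best_target;
        double bound = best_bound;
        if (best_type == CAND_COUL_CV) {
          E.n_cv_cand++;
          int o = (int)std::floor(unif_rand() * E.n_off);
          if (o >= E.n_off) o = E.n_off - 1;
          if (unif_rand() >= E.cutC[fibi * E.n_off + o])
            o = E.idxC[fibi * E.n_off + o];
          double bmol[3];
          E.barycenter(am, bmol);
          int cc[3];
          E.cellCoords(E.binPoint(bmol), cc);
          int ix = ((cc[0] + E.off[3 * o]) % E.nc + E.nc) % E.nc;
          int iy = ((cc[1] + E.off[3 * o + 1]) % E.nc + E.nc) % E.nc;
          int iz = ((cc[2] + E.off[3 * o + 2]) % E.nc + E.nc) % E.nc;
          mt = E.occC[(iz * E.nc + iy) * E.nc + ix];
          if (mt < 0 || mt == am) { E.n_cv_empty++; break; }
          bound = E.bC[fibi * E.n_off + o] * s * std::fabs(E.q[E.active]);
        }
        coul_factor_grads(E, am, mt, g1, g2);
        int li = E.active - 3 * am;
        const double* gact = g1 + 3 * li;
        const double* v = &E.vel[3 * E.active];
        double rate = E.beta * std::max(0.0, gact[0] * v[0] + gact[1] * v[1] +
                                                 gact[2] * v[2]);
        E.n_cand_coul++;
        if (rate > bound * (1 + 1e-9)) {
          E.n_violation++;
          if (E.strict) stop("Coulomb bounding rate violated");
        }
        if (unif_rand() < rate / bound) {
          E.n_ev_coul++;
          int atoms[6];
          double gr[18];
          for (int j = 0; j < 3; ++j) {
            atoms[j] = 3 * am + j;
            atoms[3 + j] = 3 * mt + j;
            for (int k = 0; k < 3; ++k) {
              gr[3 * j + k] = g1[3 * j + k];
              gr[9 + 3 * j + k] = g2[3 * j + k];
            }
          }
          if (E.variant == 0)
            lift_general_apply(E, atoms, gr, 6);
          else
            lift_straight_apply(E, atoms, gr, 6);
        }
        break;
      }
    }
    if (E.cv && best_type != CAND_BOUNDARY &&
        best_type != CAND_SAMPLE && best_type != CAND_END) {
      // active atom may have changed molecule or moved: keep bins in sync
      rebin(E, am, false);
      rebin(E, am, true);
    }
    Rcpp::checkUserInterrupt();
  }

  double vtv1 = 0, vsum[3] = {0, 0, 0};
  for (int i = 0; i < E.Na; ++i)
    for (int k = 0; k < 3; ++k) {
      vtv1 += E.vel[3 * i + k] * E.vel[3 * i + k];
      vsum[k] += E.vel[3 * i + k];
    }

  int ns = (int)E.stamps.size();
  NumericMatrix P(ns, 3);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) P(i, k) = E.Pout[3 * i + k];
  NumericMatrix finalpos(3, E.Na);
  std::copy(E.pos.begin(), E.pos.end(), finalpos.begin());

  List out = List::create(
      _["stamps"] = NumericVector(E.stamps.begin(), E.stamps.end()),
      _["polarization"] = P, _["final_positions"] = finalpos,
      _["events"] = NumericVector::create(
          _["bond"] = E.n_ev_bond, _["bend"] = E.n_ev_bend,
          _["lennard_jones"] = E.n_ev_lj, _["coulomb"] = E.n_ev_coul),
      _["candidates"] = NumericVector::create(
          _["bend"] = E.n_cand_bend, _["lennard_jones"] = E.n_cand_lj,
          _["coulomb"] = E.n_cand_coul, _["cell_veto"] = E.n_cv_cand,
          _["cell_veto_empty"] = E.n_cv_empty),
      _["bound_violations"] = E.n_violation,
      _["max_handlers"] = E.max_handlers,
      _["mean_active_speed"] = E.speed_time / std::max(E.time_tot, 1e-300),
      _["kinetic_energy_drift"] =
          std::fabs(vtv1 - vtv0) / std::max(vtv0, 1e-300),
      _["velocity_sum"] = NumericVector::create(vsum[0], vsum[1], vsum[2]));
  if (E.store_configs) {
    NumericVector cf(E.configs.begin(), E.configs.end());
    cf.attr("dim") = IntegerVector::create(3, E.Na, ns);
    out["configs"] = cf;
  }
  return out;
}

// test hook: deterministic bond candidate time for a given threshold
// [[Rcpp::export(name = ".bond_candidate_cpp")]]
double bond_candidate_test(NumericVector xi, NumericVector xj,
                           NumericVector v, double beta, List ffpars,
                           double Tend, double threshold) {
  Spcfw ff = spcfw_from_list(ffpars);
  return bond_candidate_thr(&xi[0], &xj[0], &v[0], beta, ff, Tend, threshold);
}
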