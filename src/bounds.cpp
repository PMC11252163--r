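#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cell-veto bound estimation.
//
// For each relative cell offset (outside the excluded layers) and each
// Fibonacci velocity direction, the factor event rate is maximized over
// position grids in the two cells:
//   Coulomb: a point charge in the (padded) active cell against a unit point
//     dipole in the (padded) target cell, the dipole aligned with the
//     gradient of the charge-dipole interaction; the velocity is allowed to
//     range over a spherical cap covering the Voronoi cell of the Fibonacci
//     vector. Padding accounts for atoms sitting off the tracked barycenter,
//     a 1/r quadrupole allowance for the finite charge separation of a real
//     molecule, and a residual-field constant for all periodic-image and
//     Ewald-screening corrections beyond the nearest image.
//   Lennard-Jones: two oxygens on unpadded grids (the occupancy system
//     tracks the oxygens themselves), |U'(r)| times the capped direction
//     cosine.
// Bounds are stored for unit active-atom speed and unit charge and rescaled
// at run time.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".estimate_cell_bounds_cpp")]]
List estimate_cell_bounds_cpp(IntegerMatrix offsets, NumericMatrix fib,
                              double L, int n_cells, double pad, int grid_n,
                              double beta, List ffpars, double p_dip,
                              double cap_delta, double quad_allow,
                              double hess_rest, double prefactor) {
  Spcfw ff = spcfw_from_list(ffpars);
  const int n_off = offsets.nrow(), D = fib.nrow();
  const double cell = L / n_cells;
  NumericMatrix bC(n_off, D), bLJ(n_off, D);
  const double cosd = std::cos(cap_delta), sind = std::sin(cap_delta);

  // difference grid between two cells (shared by all offsets)
  std::vector<double> gpadded(grid_n), gplain(grid_n);
  for (int i = 0; i < grid_n; ++i) {
    gpadded[i] = -pad + (cell + 2 * pad) * i / (grid_n - 1.0);
    gplain[i] = cell * i / (grid_n - 1.0);
  }
  // per-axis difference values (b - a) for padded and plain grids; the
  // difference set of two product grids is the product of per-axis
  // difference sets, so the maximization enumerates G2^3 pair differences
  int G2 = grid_n * grid_n;
  std::vector<double> diff_pad(G2), diff_plain(G2);
  for (int ib = 0; ib < grid_n; ++ib)
    for (int ia = 0; ia < grid_n; ++ia) {
      diff_pad[ib * grid_n + ia] = gpadded[ib] - gpadded[ia];
      diff_plain[ib * grid_n + ia] = gplain[ib] - gplain[ia];
    }

  double r_floor = 0.8;

  for (int o = 0; o < n_off; ++o) {
    double base[3] = {offsets(o, 0) * cell, offsets(o, 1) * cell,
                      offsets(o, 2) * cell};
    for (int d = 0; d < D; ++d) {
      double v[3] = {fib(d, 0), fib(d, 1), fib(d, 2)};
      double kmaxC = 0.0, kmaxLJ = 0.0;
      for (int jx = 0; jx < G2; ++jx)
        for (int jy = 0; jy < G2; ++jy)
          for (int jz = 0; jz < G2; ++jz) {
            double rx = min_image(base[0] + diff_pad[jx], L);
            double ry = min_image(base[1] + diff_pad[jy], L);
            double rz = min_image(base[2] + diff_pad[jz], L);
            double r2 = rx * rx + ry * ry + rz * rz;
            double r = std::sqrt(r2);
            if (r < r_floor) r = r_floor;
            double c = std::fabs(rx * v[0] + ry * v[1] + rz * v[2]) /
                       std::sqrt(r2);
            if (c > 1) c = 1;
            double cmax = c * cosd + std::sqrt(std::max(0.0, 1 - c * c)) * sind;
            if (cmax > 1) cmax = 1;
            double kern = std::sqrt(1 + 3 * cmax * cmax) / (r * r * r) *
                          (1 + quad_allow / r);
            if (kern > kmaxC) kmaxC = kern;
            // LJ grids are unpadded
            double sx = min_image(base[0] + diff_plain[jx], L);
            double sy = min_image(base[1] + diff_plain[jy], L);
            double sz = min_image(base[2] + diff_plain[jz], L);
            double s2 = sx * sx + sy * sy + sz * sz;
            double s = std::sqrt(s2);
            if (s < r_floor) s = r_floor;
            double cl = std::fabs(sx * v[0] + sy * v[1] + sz * v[2]) /
                        std::sqrt(s2);
            if (cl > 1) cl = 1;
            double clm = cl * cosd + std::sqrt(std::max(0.0, 1 - cl * cl)) * sind;
            if (clm > 1) clm = 1;
            double kl = lj_abs_dudr(s, ff) * clm;
            if (kl > kmaxLJ) kmaxLJ = kl;
          }
      bC(o, d) = beta * ff.kc * p_dip * (kmaxC + hess_rest) * prefactor;
      bLJ(o, d) = beta * kmaxLJ * prefactor;
    }
  }
  return List::create(_["bounds_coulomb"] = bC, _["bounds_lj"] = bLJ);
}
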