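---
title: "Event-chain Monte Carlo for flexible SPC/Fw water: models, bounds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-chain Monte Carlo for flexible SPC/Fw water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The sampling problem

`waterecmc` samples the canonical (Boltzmann) distribution of `N` flexible
SPC/Fw water molecules in a periodic cubic box with a *non-reversible,
approximation-free* Markov process: event-chain Monte Carlo (ECMC), a
piecewise-deterministic Markov process in continuous Monte Carlo time. A
single *active* atom moves along a straight line; the motion is interrupted
by stochastic *events* generated independently by the *factors* of the
potential, and each event transfers the motion according to a lifting
scheme. The total potential and the total force are never evaluated, there
is no time-step discretization, no interaction cutoff, and no thermostat:
the stationary law is the Boltzmann distribution exactly, at every moment
of the continuous-time evolution.

## The potential and its factors

The SPC/Fw model describes each molecule by three charged sites (O, H, H)
with, per molecule, two harmonic O–H bonds
$U_\mathrm{bond} = \tfrac{k_b}{2}(\ell-\ell_0)^2$ and one harmonic bend
$U_\mathrm{bend} = \tfrac{k_a}{2}(\theta-\theta_0)^2$, and per molecule
pair an oxygen–oxygen 12-6 Lennard-Jones term (minimum-image convention,
no tail corrections) and one *molecular Coulomb factor*: the full periodic
lattice sum over the nine charge pairs of the two molecules. The numeric
constants (`spcfw_parameters()`) are
$\ell_0 = 1.012$ Å, $k_b = 1059.162$ kcal mol⁻¹ Å⁻²,
$\theta_0 = 113.24^\circ$, $k_a = 75.90$ kcal mol⁻¹ rad⁻²,
$\varepsilon = 0.1554253$ kcal mol⁻¹, $\sigma = 3.165492$ Å,
$q_\mathrm{O} = -0.82\,e$, $q_\mathrm{H} = +0.41\,e$, with the Coulomb
prefactor fixed to the conventional force-field value
$1/(4\pi\varepsilon_0) = 332.06371$ kcal Å mol⁻¹ e⁻². Units throughout
are Å, kcal/mol, elementary charges, Da and Kelvin. Bonded atoms are
stored unwrapped (never minimum-imaged against each other); only
intermolecular distances are wrapped.

The sum of these factor potentials is the total potential; the partition
is exact and is verified to machine precision in the test suite.

## Event rates and candidate times

A factor `M` interrupts the active atom `i` with rate
$\lambda_M(t) = \beta\,\max[0, \nabla_{x_i} U_M \cdot v_i]$.
Each factor independently draws a candidate time at which the integrated
rate first reaches an exponential threshold. The package realizes this in
three ways:

* **Bonds — exact inversion.** Along a straight trajectory the bond length
  is a hyperbola in time, so the uphill increments of the harmonic
  potential accumulate in closed form between the monotonicity breakpoints
  (closest approach, equilibrium-length crossings) and the threshold
  identity is inverted analytically (`bond_event_time()`). The
  adaptive-quadrature oracle `numerical_event_time_oracle()` validates the
  inversion to 1e-8 in time. Because clamped rates are only piecewise
  smooth and adaptive quadrature can silently lose accuracy at the clamp
  kinks, the oracle first locates the boundaries of the rate's
  zero-regions by a bisection-refined scan and integrates each smooth
  piece separately.
* **Generic bounding slices.** `bounded_event_time()` upper-bounds an
  arbitrary rate on travel slices (default 0.1 Å) by the maximum of the
  rate at the slice endpoints and midpoint times a safety factor (default
  1.2), draws the candidate from the piecewise-constant bound, and leaves
  the exact correction to the thinning confirmation
  (`confirm_event()`), which accepts with probability true/bound and
  treats any bound violation as a fatal error in strict mode. Slice length
  and safety factor are performance knobs only: thinning corrects any
  overestimate.
* **Closed-form envelopes (compiled engine).** Inside the compiled event
  loop, evaluation-based slice bounds would cost one Ewald evaluation per
  slice endpoint, so the engine instead uses analytic envelope rates that
  provably dominate the factor rates on each slice:
  * bend: $\lambda \le \beta k_a (|\theta-\theta_0| + \Delta s\,\kappa)\,
    s\,\kappa$ with $\kappa = 1/r_1 + 1/r_2$ (the exact bound on
    $|\nabla_\text{atom}\theta|$) and $\Delta s$ the slice travel;
  * near-field Coulomb: the minimum of a *monopole* envelope
    $\beta |q_i| s\, k_C \sum_j |q_j| (d_j^{-2} + C_1)$ over the three
    target charges at their actual distances, and a *neutrality-aware*
    envelope $\beta |q_i| s\, k_C M_1 (2 d_b^{-3} + C_2)$ obtained from
    the mean-value theorem on the periodic charge kernel, where
    $M_1 = \sum_j |q_j|\,|\delta_j|$ is the first moment of the molecular
    charge distribution about its barycenter (inflated by 15% for thermal
    geometry fluctuations) and $d_b$ the distance to the barycenter;
  * Lennard-Jones: the interval maximum of $|U'(r)|$ over the separations
    reachable within the slice (evaluated at the interval ends and the
    inflection point of $|U'|$).

  $C_1$ and $C_2$ are *residual-field constants*: upper bounds on the
  gradient and Hessian difference between the full periodic (Ewald)
  charge kernel and the bare nearest-image kernel, estimated once per box
  by a dense scan plus a 1.5 safety margin. They absorb all
  periodic-image and screening corrections, so the envelopes are bounds
  for the full lattice-summed interaction, not only its nearest image.
  Every confirmation re-checks the bound against the exact rate and
  aborts on violation (strict mode), so an envelope failure cannot pass
  silently.

## Lifting schemes

At a confirmed event of factor `M` the lifting variables change:

* **Newtonian-pair** (bonds, Lennard-Jones; equal masses): the force kick
  — the reflection of the velocity in the factor gradient, which conserves
  $v^T M v$ and is an involution — is always applied to both atoms and the
  activity always moves to the other atom. For a head-on pair geometry it
  reduces to the equal-mass elastic collision.
* **Newtonian-general** (bend, molecular Coulomb): among the `2|M|`
  outcomes (next active atom × kicked-or-kept velocity) the choice is
  sampled with weights $\max[0, -\nabla_{x_k} U_M \cdot v'_k]$ (kicked)
  and $\max[0, -\nabla_{x_k} U_M \cdot v_k]$ (kept). When the velocity is
  kept the active atom always changes, because the pre-event rate of the
  active atom was positive.
* **Straight** variant: unit speed along a coordinate axis, velocity
  transferred unchanged; for factors of more than two atoms the target is
  sampled with ratio weights $\propto \max[0, -\nabla_{x_k} U_M \cdot v]$.
  The precise ratio rule is a package decision (the variant is otherwise
  specified through its literature); pair factors transfer
  deterministically.

## Kinetic-energy convention and resampling

The all-atom velocity has no kinematic meaning; its magnitude convention
is chosen so the expected active-atom speed is about one Å per unit Monte
Carlo time: with identity masses, $2E_\mathrm{kin} = 3 N_a \pi / 8$.
`resample_lifting()` draws a Gaussian with covariance $M^{-1}$, removes
the componentwise mean (so the velocity sum vanishes) and rescales onto
the kinetic-energy shell; the active label is uniform.

Resampling every `tau_chain` is required for irreducibility. The package
defaults follow the variant protocols: `0.2 N` (straight, with the six
axis directions cycled deterministically) and `10000 N` (Newtonian). For
*very small* systems (one to a few molecules) the Newtonian default is far
too rare: with only pair kicks along a couple of slowly rotating bond
axes, the velocity marginal mixes extremely slowly and finite-length runs
become biased by their initial velocity draw. The validation runs in the
test suite therefore set `tau_chain` to order 10 for N = 1–8; this is a
run-condition choice, not a change of the sampled distribution (any
finite `tau_chain` leaves the stationary law exact).

## Machine-precision Ewald summation

The molecular Coulomb factor is evaluated with the classic Ewald
summation in continuous space for the nine charge pairs of two neutral
molecules, including all periodic images and excluding each molecule's
self-images, under conducting ("tinfoil") boundary conditions — the
standard choice for dipole-fluctuation studies; because both charge
groups are neutral, the splitting-dependent background terms cancel
identically and no surface term arises. `ewald_settings()` auto-tunes the
reciprocal and real-space cutoffs on a probe configuration until
successive energies agree to 1e-12 relative ("machine precision" is
interpreted as 1e-12), then freezes; the default splitting length `L/4`
balances the two sums for a per-pair evaluation whose cost is independent
of `N`. The test suite verifies splitting-parameter independence below
1e-9 kcal/mol and gradients against central finite differences.

The Metropolis reference sampler needs full-system energy *differences*,
not per-pair machine precision: it uses the same Ewald identity with a
minimum-image real-space part (`alpha = 8/L`) and an incrementally
maintained total structure factor, truncated so the residual is below
1e-6 kcal/mol — six orders of magnitude below the thermal energy, and
verified against the per-pair factor sum in the tests. The exactness
claims of the ECMC engine never rest on this truncation.

## Cell-veto bundling of the far field

With `O(N)` long-range factors changing as the active atom moves, the
engine bundles all far-field Coulomb (and Lennard-Jones) factors into a
single candidate source per interaction type:

* a cubic **cell grid** (largest cells keeping expected occupancy below
  ~0.55, at least `2·excluded_layers + 2` cells per edge) tracks molecular
  barycenters (Coulomb) and oxygens (LJ), one occupant per cell with a
  surplus list; surplus molecules and everything inside the excluded
  layers (depth 2) are served by the direct envelope solvers;
* per relative cell offset and per **Fibonacci vector** (the golden-ratio
  equal-area construction with `D = 10`, `eps = 0.36`), a **cell bound**
  dominates the factor rate for any molecule placement in the two cells:
  a position grid (5 per axis) in the padded cells (padding 1.3 Å covers
  the atoms' offsets from the tracked barycenter) is combined with the
  first-moment constant `M_1`, the bare Hessian direction factor
  $\sqrt{1+3\cos^2}$, the residual constant $C_2$, and the empirical
  prefactor (default 2.0). The maximization over the velocity Voronoi
  cell is replaced by a spherical cap with half-angle equal to the
  covering radius of the Fibonacci set (estimated on a dense probe set
  and inflated by 10%), which contains every Voronoi cell;
* a **Walker alias table** per Fibonacci vector turns the set of bounds
  into one total rate `Q` and a constant-time draw of the target cell.
  Bounds are stored for unit speed and charge and rescaled to the active
  atom at run time. Empty target cells are no-events; occupied ones are
  confirmed by thinning against the exact Ewald rate.

Cell-boundary crossings of the tracked points are deterministic events
that re-bin the occupancy, so bounds always refer to the actual cells.
Correctness is independent of every quantity in this section — grids,
prefactor, padding, cap angle — because thinning corrects any
overestimate and strict mode aborts on any underestimate; they only steer
the confirmation efficiency. The test suite includes a brute-force
validity sweep at the nearest allowed cell offset and a distributional
equivalence run (cell-veto vs direct handling) on a small box.

## Metropolis reference sampler

The reversible single-atom Metropolis chain proposes a uniform
displacement of one random atom inside a per-species cube and accepts
with `min(1, exp(-beta dU))`, with `dU` from the affected factors only
(exactly the total difference, by the partition). During burn-in the
half-widths adapt per species toward a 37% target acceptance by the
multiplicative rule `delta <- delta * (acc/target)^(1/2)` per batch
(default 1000 trials); the freeze value is the geometric mean of the last
five batches, and production is strictly reversible. The adaptation rule
itself is a package decision (only the target is prescribed by the
protocol it mirrors).

## Observables and analysis

`polarization()` sums the molecular dipoles (hydrogens minimum-imaged to
their oxygen; neutrality makes each term origin-independent).
`autocorrelation()` implements the normalized product estimator without
mean subtraction (the stationary mean vanishes by symmetry);
`fit_decay()` takes replicate autocorrelation curves, forms per-lag
medians, bootstrap errors (200 resamples) and an error-weighted
log-linear fit inside the window where the median lies in [0.05, 0.8].
Burn-in removal (first 20% of each trajectory) and the window are package
decisions. `characteristic_distance()` converts autocorrelation times
into the average cumulative distance moved by the atoms: mean active
speed × tau for ECMC; `N (2<|v_H|> + <|v_O|>) tau` with Maxwell mean
speeds for molecular dynamics; acceptance × mean cube displacement
(≈ 0.961 δ per species, weighted 2/3–1/3) × tau for Metropolis,
deliberately neglecting rejection–displacement correlations.

## Synthetic boxes

`generate_water_box()` replaces an external packing/NPT pipeline: simple
cubic lattice placement at the requested density (0.97 g/cm³ default,
masses 1.0079/15.9994001 Da for the box volume), uniformly random
molecular orientations at equilibrium internal geometry, and a short
compiled Metropolis pre-equilibration (default 400 trials per molecule)
that removes lattice order and overlaps. The generator emulates a bulk
liquid box at fixed density; it does not emulate NPT density
fluctuations, interfaces, or ionic impurities, so passing tests support
the samplers' correctness on homogeneous bulk water only.

## Problem sizes and numerical choices in the tests

The suite validates stationary distributions on closed-form cases (an
isolated harmonic dimer; single-molecule bond and bend marginals), the
three-sampler cross-validation on `N = 2, L = 20 Å` (tens of thousands of
polarization samples per sampler, with Kolmogorov–Smirnov tests on
decorrelation-thinned subsamples so their p-values are valid), cell-veto
equivalence on a dilute 8-molecule box, and the logarithmic growth of the
Coulomb event rate over `N in {64, 216, 512}` from short production runs.
The equivalence box is run at 500 K: at 300 K a dilute box condenses into
a droplet whose slow cluster rearrangements dominate the decorrelation
time, while the gas phase exercises the same bundling machinery on a
homogeneous system. These sizes are chosen
so the full suite completes on a single CPU while every statistical
assertion retains four-sigma or KS `p > 1e-3` resolution. Ties in the
scheduler are broken by handler registration order (a measure-zero
event); degenerate geometries (collinear bends, zero velocities) are
guarded by explicit floors documented in the source.

## Known limitations

No pressure/virial computation, no NPT ensemble, no polarizable or rigid
water models, no cutoff-based Coulomb alternative, no reciprocal-space
mesh solver, and no multi-active-atom parallelization. The straight
variant mixes molecular orientations slowly (that inefficiency is a
finding about samplers, not a defect of the implementation), so its
validation runs are the longest in the suite.
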