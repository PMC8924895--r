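---
title: "Polarizable halide-ion/water potentials: model, fitting and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizable halide-ion/water potentials: model, fitting and optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionwater)
```

## The interaction model

`ionwater` evaluates the energy of a halide anion X⁻ (X = F, Cl, Br, I)
surrounded by water molecules through a many-body expansion

$$V_n \;=\; \sum_n V_W^{\mathrm{intra}} + V_{W\text{-}W}^{\mathrm{inter}}
          + V_{i\text{-}W}^{\mathrm{inter}},$$

where the ion–water part is the sum the package parameterizes:

$$V_{i\text{-}W}^{\mathrm{inter}} \;=\;
  V^{2B}_{\mathrm{rep}} + V^{2B}_{\mathrm{disp}}
  + V^{2B}_{\mathrm{elec}} + V^{nB}_{\mathrm{ind}}.$$

* **Repulsion** — Born–Mayer pair terms over ion–O and ion–H pairs,
  $\sum A_{ij} e^{-\beta_{ij} R_{ij}}$ with $A \ge 0$ (kcal/mol) and
  $\beta > 0$ (Å⁻¹).  The steepness is stored positive and used in a
  decaying exponential, so repulsion vanishes at large separation.
* **Dispersion** — Tang–Toennies-damped $R^{-6}$ attraction,
  $-\sum C_6^{(ij)} f_6(R_{ij},\delta_{ij})/R_{ij}^6$, with
  $f_n(R,\delta) = 1 - e^{-\delta R}\sum_{k=0}^{n}(\delta R)^k/k!$.
  The damping steepness of each pair is tied to its Born–Mayer
  $\beta$ ($\delta_{ij} = \beta_{ij}$, the `tie_delta` rule), so fitting
  $\beta$ fixes the short-range damping shape at the same time.
* **Permanent electrostatics** — smeared charges: $+q_H$ on each hydrogen,
  $-2q_H$ on the M-site displaced from the oxygen along the HOH bisector
  (fraction `m_site_fraction` of the O→H-midpoint segment; the default 0.25
  puts it ≈ 0.147 Å from O for the rigid reference monomer), and $-1\,e$ on
  the anion.  Only inter-monomer pairs interact; the ion counts as its own
  monomer.
* **Induction** — one isotropic polarizable site on O, each H and the ion.
  The dipoles solve the coupled Thole-damped equations
  $\mu_i = \alpha_i\,(E_i^{\mathrm{perm}} + \sum_{j\ne i} T_{ij}\mu_j)$,
  and $U_{\mathrm{ind}} = -\tfrac12 k \sum_i \mu_i\!\cdot\!E_i^{\mathrm{perm}}$.
  Because all sites couple, induction is genuinely many-body: the
  three-body nonadditivity of an ion plus two waters vanishes exactly when
  all polarizabilities are zero and not otherwise (this is a package test).

Units everywhere: Å, kcal/mol, electron charges, Å³ polarizabilities, with
the Coulomb constant fixed at $k = 332.0637157$ kcal·Å/(mol·e²).

### Smearing and damping formulas

The literature names "smeared charges" without committing to a formula, so
the package defines one family explicitly and uses it consistently:

* charge–charge: a Slater-type density $e^{-r/a}$ gives the screened pair
  potential $\phi = \frac{q}{r}\left[1-(1+y/2)e^{-y}\right]$, $y = r/a_{ij}$;
* charge field at a polarizable site: the gradient-consistent screen
  $1-(1+y+y^2/2)e^{-y}$ (the enclosed-charge function, always in $[0,1]$);
* dipole–dipole: the exponential-3 Thole screens
  $\lambda_3 = 1-e^{-x}$, $\lambda_5 = 1-(1+x)e^{-x}$ with
  $x = (r/A_{ij})^3$ and the polarizability-derived damping length
  $A_{ij} = (\alpha_i\alpha_j)^{1/6}/a^{1/3}$ ($a$ = `thole_dd`,
  default 0.572).  Intramonomer pairs use an enlarged $A_{ij}$
  (`thole_intra_scale`, default 2): increased intramolecular damping.

Charge-pair widths combine in quadrature; any zero width recovers the point
limit, which is how the closed-form Coulomb and induction oracles in the
test suite are exercised.  A non-positive-definite dipole interaction
matrix (the polarization catastrophe) is reported as an error rather than
silently producing unbounded energies.

### The water model is pluggable

Reproducing published TTM2/TTM3/TTM4-F/MB-pol water–water potentials is out
of scope; the package ships `simple_water_model()` — harmonic intramolecular
distortion, O–O Lennard-Jones plus the same smeared water–water
electrostatics, with charges and polarizabilities taken from the ion-water
parameter set so both halves of the model are consistent.  Any object
implementing the `water_model` contract (an `intra` and an `inter_noind`
callback; the framework solves induction over the full site set) can be
substituted, which is where i-TTM2/3/4- or MB-pol-style variants would plug
in.  Consequences: total energies for multi-water clusters are qualitative,
not comparable to published cluster energetics; everything that the tests
assert about fitting, induction and the optimizer is independent of this
choice.

## Training sets

`build_spherical_grid()` places one rigid water (r(OH) = 0.9572 Å,
HOH = 104.52°) at the origin of a body-fixed frame (C2v axis = z, H atoms in
the xz-plane, bisector toward −z) and the ion on an equidistant grid in
$(R,\theta,\phi)$.  θ and φ are restricted to [0°, 180°] by the monomer's
mirror symmetry; θ uses interior points because the polar axis is
φ-degenerate.  The default 10 × 10 × 5 grid realizes the ~500-point design
with $R \in [2, 8]$ Å.

Reference energies get the weights

$$w(E) = \left(\frac{1}{E - E_{\min} + D_E}\right)^2,$$

maximal at the training minimum and decaying with energy; $D_E$ (default
2 kcal/mol) sets the range of favourably weighted energies.
`make_synthetic_reference()` evaluates a known ground-truth parameter set on
the grid and adds seeded Gaussian noise, giving fit-recovery fixtures with
a known answer.  What the synthetic generator emulates is the *shape* of a
coupled-cluster-quality dimer surface under the model's own functional
form; it does not emulate basis-set effects, BSSE, monomer distortion or
any model-form error of real reference data (except where a test
deliberately breaks the $\delta = \beta$ tie to create such mismatch), so
green recovery tests certify the estimator, not the physics of any
published parameter set.

## Two-stage fitting and active learning

`two_stage_fit()` follows the asymptotics-first protocol:

1. **Stage 1** solves the two $C_6$ coefficients by weighted linear least
   squares (truncated SVD, relative cutoff $10^{-10}$) on the long-range
   subset, with damping ≈ 1 and repulsion neglected — both excellent
   approximations at $R \ge 6$ Å.
2. **Stage 2** freezes $C_6$ and runs the active-learning loop for
   $(A, \beta)$: the two steepnesses move through Nelder–Mead simplex steps
   (in log space, one restart on stagnation) while the amplitudes are
   re-solved by SVD at every simplex evaluation (variable projection).
3. **Joint refinement** (default one pass, `refine_cycles`) releases the
   $C_6$ and repeats the loop warm-started from stage 2.  The long-range
   stage anchors the asymptotic behaviour and provides consistent starting
   values, but dispersion carries very little statistical weight at large
   $R$: the linearized covariance of a $C_6$ estimate from long-range
   points alone is noise-limited (tens of percent at 0.05 kcal/mol noise),
   while the full-set joint solve brings it to a few percent.
   `refine_cycles = 0` gives the strict protocol; stage 2 then provably
   never alters $C_6$ (asserted bitwise in the tests).

The **active-learning reweighting loop** around each fit: minimize the
weighted $\chi^2 = \sum_N w_N (V_{\mathrm{model}}(N) - \Delta E_{\mathrm{ref}}(N))^2$;
check convergence (mean absolute error below `mean_error_tol`, maximum
error below `pointwise_error_tol`, or the iteration cap); otherwise boost
the weights of every point whose error exceeds `error_fraction_threshold`
(default 0.5) times the current maximum error by $1 + \gamma_0 d^{\,t}$
(defaults $\gamma_0 = 1$, $d = 0.7$ — the boosts decay geometrically, a
"gradual descent"), renormalize the weights to mean 1, and refit.  An
iterate that fails to improve the RMS error is rejected and the loop halts.
Setting the threshold above 1 disables boosting, which is exactly the
single-pass baseline (`single_pass_fit()`) used in the paired comparison:
on a surface the tied-damping model cannot represent exactly, with a
sparsely sampled repulsive wall, the reweighting loop ends with a smaller
maximum pointwise error than the single-pass fit at the same simplex
budget.

Two statistical notes, both reflected in the tests.  Energy-based weights
exist to emphasize the well region when the model must compromise; under
homoscedastic synthetic noise they are *inefficient* (they inflate the
variance of the weakly identified $C_6^{(H)}$ several-fold), so recovery
under noise is assessed with uniform initial weights, which the loop
accepts as readily as energy weights.  And with noisy data the loop's
boosts chase noise, so the noisy-recovery protocol disables them.

## The evolutionary-programming optimizer

Minimum-energy structures come from self-adaptive EP: individuals are
$(\chi_i, \eta_i)$ pairs of coordinates and per-coordinate step sizes,
mutated as

$$\chi'(j) = \chi(j) + s_g\,\eta(j)\,N_j(0,1), \qquad
  \eta'(j) = \eta(j)\exp\!\big(\tau' N(0,1) + \tau'' N_j(0,1)\big),$$

with $\tau' = 1/\sqrt{2n}$, $\tau'' = 1/\sqrt{2\sqrt n}$ by default, and a
global step scale $s_g = \delta_0\,\delta_j^{\,g}$ (defaults
$\delta_0 = 0.15$, $\delta_j = 0.85$).  "Moves 85% less each generation"
is ambiguous; the default multiplies the step by 0.85 per generation, and
`decay_mode = "literal"` provides the ×0.15 reading.  Survivors of the
joint 2M parent–child pool are chosen by q-opponent tournament (wins by
lower energy; ties broken toward lower energy, and the pool's best
individual always survives, which makes the best-energy series
non-increasing).  Convergence follows the threshold rule — best-energy
change below `energy_threshold` (default 0.01 kcal/mol) between
consecutive generations — guarded by a `patience` of consecutive
sub-threshold generations (default 3) against premature stops.
`seed_from_water_cluster()` builds starting structures by substituting the
ion for each water in turn, and rigid mode moves each monomer as a rigid
body (translation + Rodrigues rotation genes) so any water model stays in
its validity domain.

Three guards, all off-by-default-compatible with the bare scheme and all
motivated by measured failure modes on Lennard-Jones validation clusters:

* `eta_min` (default 10⁻³ Å) floors the strategy parameters.  Without it,
  self-adaptive EP collapses its step sizes (η drifting below 10⁻¹⁰)
  long before a rough structure has relaxed, freezing the search.
* `container_radius` pulls sites farther than a radius from the cluster
  centroid back onto the sphere after mutation.  Without it, searches
  "evaporate" an atom past the attraction range, never recapture it, and
  converge to an (n−1)-cluster plus a free atom.
* `ep_global_search()` composes plain `optimize_cluster()` runs into a
  two-phase protocol: non-decaying exploration (η floor active) from a
  list of diverse seeds, then slowly decaying annealing cycles
  ($\delta_0 = 0.05$, $\delta_j = 0.97$, tight threshold) that polish the
  best candidates to the bottom of their basins.  Restart rounds
  (default 2) then repeat the pair seeded from the incumbent best
  structure: the EP initialization's own uniform (0, Δ) offsets shake a
  compact near-minimum into neighbouring basins, which samples low-lying
  minima far more effectively than fresh random geometries, and the
  incumbent is only ever replaced by something better.  On LJ₇ this
  reproduces the global minimum −16.5054 ε to better than 10⁻³ ε against
  an independent multistart local-optimization oracle; the default
  decayed schedule alone is a local refiner (it is meant for structures
  seeded from database minima) and stalls on rough seeds.

Note the interplay between the threshold rule and final precision: a
0.01 kcal/mol per-generation rule stops a run once *increments* fall below
0.01, which bounds the achievable precision near that threshold.  The
benchmark polish phases therefore use a much tighter threshold; production
ion-water runs keep the 0.01 default.

## The benchmark protocol

`method_energy_table` objects hold per-structure interaction energies
$\Delta E = E_{X^-(H_2O)_n} - E_{(H_2O)_n} - E_{X^-}$ for a named method —
evaluated by the package for model potentials (`model_energy_table()`), or
ingested from TSV for external quantum-chemistry methods, which the package
never runs.  `percent_delta()` reports
$\delta = 100\,(E_{\mathrm{model}} - E_{\mathrm{ref}})/|E_{\mathrm{ref}}|$
(the sign convention is ours; the denominator uses the reference magnitude),
`scan_error_summary()` the mean absolute error along an ion-displacement
scan, and `comparison_report()` assembles per-structure, per-group
(per-halide), correlation (slope/intercept/RMSD) and max-normalized
average-error summaries — normalization divides by the worst method, so
bars lie in (0, 1] with the worst at exactly 1.  Missing structures are
reported, never imputed; zero reference energies yield NA with a warning.
All numbers land in deterministic TSV files first; plotting is left to the
caller.

Ion-displacement scans (`ion_scan_path()`) place the ion at
$\mathrm{COM} + s\,(\mathbf{r}_{\mathrm{ion}} - \mathrm{COM})$ with the
water frame fixed: $s = 0$ is the center of mass, $s = 1$ the original
minimum, $s > 1$ the dissociative region.  The default step schedule
(0, 0.2, …, 1.5) is dense near the minimum.  Whether the center of mass
includes the ion is exposed in both the scan and the surface-plane
analysis; the plane analysis defaults to including it, the scan to the
water-only COM so the path does not depend on the moving ion.

## Numerical choices

* Tang–Toennies: forward complement for $\delta R > n+1$, complementary
  tail series below (avoids catastrophic cancellation; both agree with an
  independent series oracle to 10⁻¹⁰ relative).
* Induced dipoles: damped fixed-point iteration (mixing 0.65,
  tolerance 10⁻¹⁰ e·Å, 200 iterations) with a Cholesky direct solve as
  fallback and cross-check; iterative and direct routes agree to
  10⁻⁸ e·Å on randomized 4–10-site systems.
* SVD truncation at 10⁻¹⁰ relative; rank-deficient designs return the
  minimum-norm solution.
* Degenerate geometry (coincident sites, ion at the COM, overlapping grid
  points) and non-finite objective values are errors, not warnings.
* Test problem sizes: 500-point grids, 100 random solver systems, LJ₄/LJ₇
  benchmarks with 3/12 exploration seeds — sizes chosen so the full suite
  exercises every claim at desk scale.

## Known limitations

* The shipped water model is a reference implementation; quantitative
  multi-water energetics require plugging in a quantitative water model.
* Published i-TTM parameter tables are not bundled (they live in the
  source article's appendix); `read_params()` loads user-supplied JSON
  files, and the package's own parameter sets are synthetic or toy and are
  labelled as such.
* No analytic gradients, periodic boundary conditions, Ewald summation, or
  counterpoise/BSSE handling; geometry-dependent monomer charges (dipole
  moment surfaces) are replaced by the fixed-charge template.
* The EP optimizer is a stochastic global method: results are
  reproducible under a fixed seed, and the two-phase protocol is validated
  on LJ clusters, but no run certifies global optimality on arbitrary
  potentials.
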