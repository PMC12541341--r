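---
title: "Methods: free-energy analysis of ion pairing at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy analysis of ion pairing at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairfes)
```

# Scope and model

`pairfes` implements the analysis layer that turns biased molecular
simulations of an ion pair in water — calcium and carbonate being the
motivating system — into standard-state thermodynamics, together with the
structural and dynamical observables that characterise such simulations
(radial distribution functions, coordination numbers, interfacial electron
densities, diffusion with finite-size extrapolation, residence times,
lattice constants) and a long-range electrostatic layer built from
Gaussian charges at nuclei and Wannier centroids.

The expensive physics upstream (a first-principles-quality interatomic
potential, explicit water) is replaced at desk scale by seeded stochastic
generators whose statistical structure is exactly what the analysis
assumes.  Every quantitative claim the test suite makes is therefore a
statement about machinery, not about real water: passing tests show that
*given* samples from a known distribution the pipeline recovers the right
free energies, not that the toy potential is an accurate model of
CaCO~3~(aq).

Units are fixed package-wide: Å, ps, K, kJ/mol; Boltzmann's constant
`kb_kjmol = 0.008314463` kJ/mol/K and the Coulomb constant
`coulomb_kjmol_ang = 1389.35458` kJ·Å/mol (e²/4πε₀).  The default
temperature is 330 K throughout, matching the simulation temperature the
underlying density-functional model requires to mimic room-temperature
water.

# The toy sampler

`langevin_sample()` integrates the overdamped (Euler–Maruyama) update

$$x \leftarrow x - \frac{\Delta t}{\gamma}\nabla U + \sqrt{2 D\,\Delta t}\,\eta,
\qquad D = k_\mathrm{B}T/\gamma,$$

with friction γ in ps⁻¹.  Only the stationary distribution matters for
every downstream check, so no inertial dynamics, thermostats or barostats
are involved; the drift is written as Δt/γ so the zero-temperature limit is
plain gradient descent.  Every generator is a pure function of its seed
(the seed is logged on each run), and divergence (non-finite or exploding
coordinates) aborts with a diagnostic rather than returning garbage.

The ion pair is modelled as a *single three-dimensional relative
coordinate* moving in a radial potential (`pair_potential()`).  Because the
dynamics are genuinely 3D, the sampled distance distribution automatically
carries the \(4\pi r^2\) configurational-entropy factor that the
entropy-corrected potential of mean force (PMF) machinery removes — the
ideal-pair null (`flat_sphere_potential()`, zero potential inside a
reflecting sphere) samples \(p(r)\propto r^2\) exactly and is the
executable control for that correction.

## The model pair potential

`pair_potential()` is a sum of Gaussian basins, a screened-Coulomb tail
\(q_1q_2\,k_e/(\varepsilon r)\) and a harmonic inner wall.  The shipped
presets (`preset_pair_potential()`) mimic the qualitative shape of the
calcium–carbonate pairing profile: a deep bidentate basin at 2.9 Å
(12 kJ/mol, width 0.17 Å), a shallower monodentate basin at 3.4 Å
(7 kJ/mol), a solvent-reorganisation hump at 4.05 Å (+3 kJ/mol) and a
solvent-shared basin at 5 Å (5 kJ/mol, width 0.4 Å), with charge product
−4 e² and dielectric constant 102 — the dielectric constant of the
underlying water model, deliberately larger than the experimental 78.
They are hand-chosen shapes, versioned with the preset, and are *not* fits
to any published curve.

Two modelling choices deserve a note:

* **The tail ramps on over 6–10 Å.**  Bulk dielectric screening is
  meaningless for ions in contact, where the explicit solvation-shell
  structure (the basins) carries the interaction; applying
  \(E(r) = -4k_e/(\varepsilon r)\) down to contact would bury the basins
  under an unphysical −19 kJ/mol at 2.9 Å.  The cubic on-ramp hands over
  from structured to screened behaviour across the second solvation shell,
  which reproduces the observed pattern that the PMF tracks the analytic
  screened interaction only beyond roughly 8 Å.
* **The short-range counterpart truncates the tail over 6–12 Å.**  A model
  with a 6 Å interaction cutoff still shows water-mediated pair
  correlations out to roughly twice the cutoff, so its PMF reaches zero
  around 12 Å; the `caco3_sr` preset switches the surviving tail back to
  zero across that window.

# OPES biasing

`opes_run()` couples the sampler to an on-the-fly probability enhanced
sampling bias on the scalar CV.  A weighted kernel density estimate
\(\tilde P(s)\) is updated every `pace` steps (default 500), each kernel
deposited with weight \(e^{\beta V(s)}\), and the bias is

$$V(s) = \left(1-\tfrac1\gamma\right) k_\mathrm{B}T
\log\!\left(\frac{\tilde P(s)}{\max_s \tilde P(s)} + \epsilon\right),
\qquad \epsilon = e^{-\beta\Delta E/(1-1/\gamma)},$$

with barrier parameter ΔE = 30 kJ/mol and bias factor
\(\gamma = \Delta E/k_\mathrm{B}T\) unless overridden.  Normalising by the
maximum of \(\tilde P\) fixes the additive gauge so that
\(\max_s V \le (1-1/\gamma)\Delta E\) holds *by construction* — the
bounded-bias invariant — while leaving every reweighted quantity unchanged
(reweighting is gauge invariant).  Kernels have fixed bandwidth and are
accumulated on a 500-bin grid without compression; both simplifications
are adequate at toy scale and easy to verify.  Harmonic walls
(`wall_spec()`, default κ = 20 kJ/mol/Å², i.e. 2×10³ kJ/mol/nm² in the
quadratic-wall unit convention) confine the CV; wall energies are recorded
separately from the adaptive bias.

The quasi-static convergence flag compares the bias against a snapshot
taken at 90% of the scheduled updates: the run is `converged` when the
net L∞ drift per update over that final window is below 10⁻³ of the bias
norm (floored at \(k_\mathrm{B}T\) so that flat landscapes, whose bias is
everywhere near zero, are handled sensibly).  Per-update noise is *not*
used, because kernel-level fluctuations never vanish.

# Reweighting and run averaging

`reweight_fes()` implements umbrella-sampling-style reweighting of a
quasi-statically biased run: each recorded sample enters a histogram over
the requested CV axes with weight \(e^{\beta(V + V_\mathrm{wall})}\), and
\(F(s) = -k_\mathrm{B}T\log\) of the accumulated weight, minimum-
subtracted, with unvisited bins flagged `NA` rather than zero-filled.  The
reweighting axes need not be the biased CVs.  The first 25% of each run is
dropped by default in the association pipeline, where the bias is still
filling in.

`multi_run_fes()` averages independent runs after fixing the common
additive gauge: each run's surface is shifted by its Boltzmann-weighted
mean free energy over the *anchor basin* — the bins of the pooled surface
within 2 kJ/mol of its minimum — and the bin-wise mean and standard error
are returned.  Anchoring to a Boltzmann-weighted basin mean rather than a
single bin avoids tying the gauge to one noisy histogram cell.

# From surface to thermodynamics

The radial free energy G(r) from reweighting contains the shell-volume
entropy; `entropy_correct()` forms the PMF

$$W(r) = G(r) + k_\mathrm{B}T\ln(4\pi r^2),$$

which is flat for an ideal pair.  Two alignment conventions fix the
absolute level required by the association integral: `align_tail_zero()`
subtracts the unweighted mean of W over `[2 r_c, window end]` (short-range
models, whose PMF vanishes beyond twice the interaction cutoff
r_c = 6 Å), and `align_tail_coulomb()` subtracts the mean of
\(W - E\) over the fit window so the curve lands on the screened
interaction \(E(r) = q_1q_2 k_e/(\varepsilon r)\) (long-range models).
The default window is 12–15 Å: it starts at the 12 Å landmark where the
short-range PMF reaches zero and ends 1 Å inside the 16 Å wall used by the
sampling pipeline; the width is a package choice, as no canonical value
exists.

`association_delta_g()` then evaluates the standard-state association free
energy

$$\Delta G = -\frac1\beta \ln\, C_0 \int_0^{r^*} \!\!4\pi r^2
e^{-\beta W(r)}\,dr,$$

with \(C_0^{-1} = 1660\) Å³ (one formula unit per 1 M volume;
`standard_state_volume()` reproduces 1660 to 3 significant figures from
Avogadro's number) and r* = 14 Å, the Bjerrum-length convention defining
the associated state for a 2:2 pair — treated as a given constant, not
recomputed from a formula.  Quadrature is composite Simpson on the native
grid (with a 3/8 tail when the interval count is odd and an interpolated
terminal node when r* falls between grid points); the hard-core region
below the first grid point contributes zero because \(e^{-\beta W}\)
vanishes there, and a note is emitted when that first point exceeds 1 Å.
Uncertainties on ΔG are standard errors over independent runs, obtained by
recomputing ΔG per run — never by propagating bin-wise errors — and
reported in the compact `−8.5(5)` notation (`format_uncertainty()`).

`dielectric_rescale()` swaps the tail dielectric beyond the fit window
start and returns the change in ΔG; with the presets, moving from the
model's ε = 102 to the experimental 78 strengthens association by a few
tenths of kJ/mol, the expected sub-kJ/mol sensitivity.

## The end-to-end pipeline and its problem sizes

`pair_association_pipeline()` chains all of the above: four independent
OPES runs of 10⁶ steps (timestep 4×10⁻⁴ ps, friction 0.2 ps⁻¹, upper wall
at 16 Å, 0.1 Å bins over 2–16 Å), reweighting with 25% burn-in, run
averaging, entropy correction, alignment and the association integral,
plus the deterministic quadrature of the generator potential as ground
truth.  The friction and timestep were chosen once so that a run completes
a few hundred basin–tail round trips (the statistic that controls the ΔG
error) while keeping the per-step displacement safely below the narrowest
basin width; with these sizes the recovered ΔG agrees with the quadrature
truth to about 0.2 kJ/mol (root mean square over seeds), comfortably inside
the 0.5 kJ/mol the package's acceptance checks demand.  On the presets the
chain gives ΔG ≈ −6.7 kJ/mol (short-range, zero-tail aligned) and
≈ −9.7 kJ/mol (long-range, Coulomb-aligned): long-range electrostatics
strengthen association by about 3 kJ/mol, and this ordering is strict and
reproducible across seeds.

# Landscape topology

`locate_basins()` reports local minima of the visited region within a
configurable bin radius, resolving plateau ties to the lowest row index
(flagged).  `minimax_barrier()` computes the exact minimax pass value
between two regions by flooding bins in order of increasing free energy
with a union–find structure — equivalent to binary search on a threshold
but in one sweep — and returns one realising path (breadth-first search
restricted to bins at or below the pass).  Disconnected regions give an
infinite barrier and a flag.  `state_free_energy_difference()` integrates
\(-k_\mathrm{B}T\log\) of Boltzmann sums over two regions; bin volumes
cancel on a regular grid.  The analytic protonation landscape
(`proton_transfer_surface()`) provides a differentiable 2D test surface
with valleys pinned exactly at coordination numbers 0 and 1 and a saddle
that rises from ~18 kJ/mol at contact to ~48 kJ/mol beyond 6 Å separation,
so barrier machinery can be exercised against construction-known answers.

# Structural and dynamical observables

* `rdf()` uses standard pair-count normalisation against the ideal-gas
  shell density under the minimum image (half-box range check; self-pairs
  excluded; identical species counted once per unordered pair).
* `coordination_sharp()` uses a *closed* boundary (a neighbour exactly at
  the cutoff counts) — an arbitrary tie-break made explicit and tested.
  `switch_cubic()` implements the cubic switching function
  \((y-1)^2(1+2y)\), weight 1 at D0, 0 at Dmax, 0.5 at the midpoint, C¹ at
  both ends; `coordination_smooth()` builds the differentiable
  coordination CV from it.
* `electron_density_profile()` sums per-species z-histograms weighted by
  electron counts (O 8, H 1, C 6, Ca 20), with the origin at the mean
  height of the topmost Ca layer (single-linkage clustering of Ca heights
  with a 1 Å gap threshold).  Electron conservation is exact, including
  under the optional Gaussian smoothing, which renormalises to the
  original total.  The profile carries its normalisation metadata
  (lateral area, bin width) so either per-volume or per-cell conventions
  can be derived.
* `einstein_diffusion()` fits the mean squared displacement over 10–50% of
  the trajectory, with time origins spaced at least one fit-window apart
  to limit correlation, and converts slope/6 to the 10⁻⁵ cm²/s scale
  (1 Å²/ps = 10 × 10⁻⁵ cm²/s).  A log–log MSD exponent far from 1 (outside
  0.7–1.3) flags non-diffusive input, which catches ballistic misuse more
  reliably than r² of the linear fit.  `finite_size_extrapolate()` is
  ordinary least squares of D against 1/L.
* `residence_time()` is a survival-function estimator: excursions shorter
  than the transient tolerance t* (default 2 ps) are bridged, S(t) is the
  fraction of bound time origins still continuously bound at t, and τ
  comes from an exponential fit.  This estimator is a documented package
  convention — the experimental literature it echoes does not define one.
* `lattice_constants()` divides supercell edge means by replication counts
  with block-averaged standard errors.

# Wannier-centroid electrostatics

`charge_table()` records the valence charges O +6, C +4, H +1, Ca +10 and
−8 per Wannier centroid.  In the default *effective* calcium mode Ca
enters as a bare +2 with no centroid (its polarisation being a short-range
matter); the *explicit* mode keeps +10 and a Ca centroid.  Whether an
upstream model retains or drops Ca centroids is genuinely ambiguous, so
both modes are supported and the choice is explicit in every charge-table
object.  `assign_centroids()` attaches exactly four Wannier centers to
each host atom by greedy nearest assignment plus 2-exchange rebalancing —
optimal for physically separated molecules, and verified against full
enumeration at small size — and forms the centroid displacement as the
minimum-image mean of the four center displacements (displacements beyond
1 Å and assignments beyond 1.5 Å are flagged).

`gaussian_ewald_energy()` evaluates the periodic electrostatic energy of
spherical Gaussian charges entirely in reciprocal space: with the spread
convention \(\rho_i \propto e^{-\beta_i^2 r^2}\) (default β = 0.1 Å⁻¹) the
form factor \(e^{-k^2/4\beta_i^2}\) truncates the sum after a handful of
wave vectors, so no real-space Ewald split is needed — valid precisely
because the spreads are wide.  The k = 0 term is omitted (tinfoil
boundary), the Gaussian self-energy \(k_e q_i^2\beta_i/\sqrt{2\pi}\) is
subtracted, charged cells receive the uniform-background correction with a
logged note, and the wave-vector cutoff π/spacing is guarded: spreads too
sharp for the requested grid raise an error that names a usable spacing.
Forces are the analytic gradient.

`direct_sum_oracle()` is the independent check: pairwise
\(q_iq_j\,\mathrm{erf}(\beta_{ij} r)/r\) sums over cubic image shells.
Because the bare lattice sum is conditionally convergent, the cube-shape
dipole term \(2\pi k_e|M|^2/3V\) is subtracted — landing on the same
tinfoil convention — and the remaining algebraic tail (higher-multipole
surface terms) is removed by fitting \(E_n = E + a/n^2 + b/n^3 + c/n^4\)
over the outermost shells.  With 16 shells this agrees with the
reciprocal-space evaluation to better than 10⁻⁴ kJ/mol on random neutral
site sets, and a single point-like charge lands on the simple-cubic
Wigner constant −2.8373 k_e q²/2L, which would fail loudly if the
self-energy bookkeeping were wrong.

# Degenerate inputs and numerical tie-breaks

Parsers report the offending line number; a missing bias field reads as
zero with a warning.  Reweighting warns when all samples fall in one bin
and silently counts (but reports) samples outside the grid.  Plateau ties
in basin location go to the lowest bin index, flagged.  A constant surface
has no basins (warning).  Never-bound residence input yields `NA` with a
flag rather than a number.  Minimum-image components lie in (−L/2, L/2]
with the upper boundary closed.  The trajectory wrapping convention is
recorded in the file comment line and checked by consumers (the MSD warns
on wrapped input).

# What the tests do and do not show

The suite validates machinery against closed forms (equipartition,
ideal-pair flatness, the association integral of W ≡ 0, the two-sample
reweighting identity), against independent oracles (27-image minimum-image
scan, exhaustive minimax enumeration, the direct electrostatic sum,
finite-difference gradients, Monte-Carlo committee statistics) and against
generator ground truth (diffusion, residence, association ΔG).  Real
systems differ in ways the toys deliberately omit: explicit solvent
degrees of freedom, multiple coupled CVs, inertial dynamics, force-field
error.  Conclusions about CaCO₃ itself require the upstream simulations
this package analyses, not the package alone.
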