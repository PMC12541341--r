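# pairfes

Free-energy and structural analysis of ion pairing from enhanced-sampling
simulations, at desk scale.

## The problem

The association of Ca²⁺ and CO₃²⁻ in water — the first step of calcium
carbonate nucleation — is quantified by the standard-state association free
energy obtained from the radial pair free energy G(r) of a biased
(enhanced-sampling) simulation. Getting from biased samples to a number
involves a chain of analysis steps, each with its own conventions and
pitfalls: reweighting the bias out of the sampled distribution, removing
the 4πr² configurational-entropy term to form the potential of mean force
W(r) = G(r) + k\_BT ln(4πr²), fixing the absolute level of W by aligning its
tail (to zero for short-range models, or to the screened Coulomb
interaction E(r) = q₁q₂k\_e/(εr) for models with explicit long-range
electrostatics), and finally integrating

ΔG = −k\_BT ln [ C₀ ∫₀^r\* 4πr² e^(−βW(r)) dr ],

with C₀ the 1 M concentration (one formula unit per 1660 Å³) and
r\* = 14 Å the separation below which the pair counts as associated.

`pairfes` implements that chain — plus the observables that surround it in
practice (radial distribution functions, sharp and cubic-switch
coordination numbers, interfacial electron-density profiles, Einstein
diffusion with 1/L finite-size extrapolation, residence times, lattice
constants) and a periodic electrostatics layer for spherical Gaussian
charges at nuclei and Wannier centroids, verified against a direct-sum
oracle. Because the upstream machine-learning potential and explicit-water
MD are out of reach on a desk, the package ships seeded toy generators
(overdamped Langevin dynamics on model pair potentials, an OPES-style
adaptive bias with harmonic walls, Brownian walks, two-state residence
kinetics, layered interfaces, committee force sets) that reproduce exactly
the statistical structure the analysis assumes, so every step is testable
against closed forms and independent oracles.

It is aimed at molecular-simulation practitioners who want a transparent,
tested reference implementation of this analysis chain in R, tibble-first
and pipe-friendly.

## Worked example

The full pipeline — four independent OPES-biased runs of the toy ion pair,
reweighting, run averaging, entropy correction, tail alignment, and the
association integral — against the short-range and long-range presets:

```r
library(pairfes)

sr <- pair_association_pipeline(preset_pair_potential("caco3_sr"),
                                "zeroed_tail", seed = 1)
lr <- pair_association_pipeline(preset_pair_potential("caco3_lr"),
                                "coulomb_tail", seed = 2)
sr
#> <assoc_pipeline> DeltaG = -6.43(8) kJ/mol (zeroed_tail; true quadrature -6.737; 4 runs)
lr
#> <assoc_pipeline> DeltaG = -9.7(1) kJ/mol (coulomb_tail; true quadrature -9.742; 4 runs)

glance(sr)
#> # A tibble: 1 × 7
#>   delta_g     se label    delta_g_true alignment   n_runs all_converged
#>     <dbl>  <dbl> <chr>           <dbl> <chr>        <int> <lgl>
#> 1   -6.43 0.0754 -6.43(8)        -6.74 zeroed_tail      4 TRUE
```

Reading the numbers: the sampled short-range ΔG of −6.43(8) kJ/mol (the
parenthesis is the standard error over the four runs, in the last digit)
recovers the deterministic quadrature of the generator potential
(−6.74 kJ/mol) to within a few tenths of kJ/mol, and the Coulomb-aligned
long-range variant is ~3 kJ/mol more negative — long-range electrostatics
strengthen association, the qualitative signature this analysis exists to
expose. `autoplot(sr$pmf)` draws the aligned W(r); `locate_basins()`,
`minimax_barrier()` and `state_free_energy_difference()` analyse the
landscape topology (the deepest basin of the sampled surface sits at
2.95 Å, the bidentate contact pair).

Other entry points follow the same pattern: `rdf()`, `coordination_sharp()`,
`switch_cubic()`, `electron_density_profile()`, `einstein_diffusion()` +
`finite_size_extrapolate()`, `residence_time()`, `lattice_constants()`,
`assign_centroids()` + `build_charged_sites()` + `gaussian_ewald_energy()`.
Readers and writers cover extended-XYZ trajectories (`read_extended_xyz()`),
COLVAR-style CV tables (`read_cv_table()`) and gridded free-energy text
files (`read_fes_grid()`).

See the methods vignette (`vignettes/pairfes-methods.Rmd`) for the models,
conventions, numerical choices and limitations.

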