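# funnelmeta

Desk-scale toolkit for **funnel-metadynamics binding analysis** of the kind
used to dissect how ligands regulate a nuclear receptor's ligand-binding
domain. It is aimed at computational chemists and structural
bioinformaticians who want the *analysis machinery* of such a study —
restraint geometry, collective variables, well-tempered bias bookkeeping,
free-energy surfaces, absolute binding free energies, and the ensemble
analytics that interpret the basins — in a tested, scriptable R package,
validated end to end on toy systems with exact ground truth.

## The models at its core

**Funnel restraint + standard-state correction.** A cone of half-aperture
α merges into a cylinder of radius R<sub>cyl</sub> at axial distance
Z<sub>cc</sub> (defaults 1.1 rad, 0.1 nm, 0.5 nm); a one-sided harmonic
wall confines the ligand. Because the unbound state is restricted to a
cylinder of known cross-section, the binding constant follows from the
axial potential of mean force W(z):

    Kb = pi * Rcyl^2 * Int_site exp(-beta (W(z) - W_unbound)) dz
    dG0 = -kB T ln(Kb C0 NA),   Kd = C0 exp(dG0 / RT)

**Collective variables.** CV1 is the ligand–protein centre-of-mass
distance; CV2 is a smooth native-contact count over a frozen pair list,

    S(X) = sum_i 1 / (1 + exp(beta (r_i - lambda r0)))

with beta = 50 nm^-1, lambda = 1.8, r0 = 0.45 nm.

**Well-tempered metadynamics.** Gaussian hills of initial height 1 kJ/mol
deposited on a pace, each damped by `exp(-V/((gamma-1) kB T))`; the
surface is recovered as `F = -(gamma/(gamma-1)) V_hills`. A BAOAB Langevin
integrator (compiled, seed-reproducible) exercises the full protocol on
analytic presets, including a 3-D spherical trap inside a funnel and a
randomly re-oriented constant-force egress rule (16 kcal/mol/Å force,
100 fs checkpoints, 0.025 Å threshold).

**Ensemble analytics.** Kabsch superposition, Cα dynamic cross-correlation
maps (DCC in [-1, 1], 0.4 display threshold), heavy-atom contact
occupancy, dihedral-window backbone helicity, mutant-vs-wild-type RMSF
increments, and Cα anchor-distance statistics.

## Worked example

Sample a tilted double well (barrier 20 kJ/mol, basin offset ~3 kJ/mol)
with well-tempered metadynamics, rebuild the surface, find its basins and
saddle, and compare the basin free-energy difference against quadrature:

```r
library(funnelmeta)

tw  <- make_toy("double_well_1d", timestep = 0.005)
p   <- metad_params(height0 = 1.2, sigma = 0.1, pace = 250, bias_factor = 16)
run <- langevin_metad_run(tw$system, p, cvs = "x", n_steps = 1e6,
                          x0 = c(-1, 0, 0), seed = 11, stride = 500,
                          grid = list(x = c(-2.5, 2.5, 2001)))
run
#> <metad_run> preset 'double_well_1d', 1000000 steps, 2001 frames, 4000 hills

fes <- reconstruct_fes(run$hills, list(x = seq(-2, 2, length.out = 801)))
basins <- find_basins(fes, depth_min = 5)
basins[, c("label", "x", "value", "depth")]
#>       label     x    value     depth
#> 1 Minimum 1 -1.02 0.000000 107.93525
#> 2 Minimum 2  0.98 3.717683  18.23015

s <- saddle_estimate(fes, basins[1, ], basins[2, ])
sprintf("saddle at x = %.3f, barrier %.2f kJ/mol", s$point, s$barrier)
#> "saddle at x = 0.085, barrier 21.95 kJ/mol"

sprintf("basin dF: metadynamics %.2f vs quadrature %.2f kJ/mol",
        basin_delta_f(fes), tw$truth$delta_f)
#> "basin dF: metadynamics 2.98 vs quadrature 2.92 kJ/mol"
```

The two basins sit at x ≈ ±1 with the right-hand one ~3 kJ/mol higher
(the planted tilt), the saddle sits at the barrier top near x = 0, and
the sampled basin free-energy difference reproduces the quadrature truth
to a few tenths of kJ/mol.

Binding free energies come from an axial profile plus the funnel
geometry:

```r
geom <- funnel_geometry()                     # Zcc 0.5 nm, Rcyl 0.1 nm, alpha 1.1 rad
z    <- seq(-0.2, 2, length.out = 1101)
fes  <- free_energy_surface(list(z = z), -20 * exp(-z^2 / 0.08),
                            reference = "plateau", temperature = 300)
binding_delta_g(fes, geom, bound_region = c(-0.2, 0.7),
                unbound_region = c(1, 1.8))
#> <binding_estimate>
#>   Delta G = -1.411 kcal/mol (standard state 1 M, T = 300 K)
#>   Kd = 9.379e+07 nM   [kd = C0 * exp(dG/RT)]
```

`tidy()` / `glance()` methods give broom-style tibbles, and `autoplot()`
draws surfaces, DCC maps and hill-height decay. Synthetic ensembles with
planted correlation, helicity, contact and fluctuation structure come
from `make_ensemble()`, which attaches its realised ground truth for
estimator checks. A thin CLI over the same functions is installed at
`inst/scripts/funnelmeta` (`funnelmeta --help`).

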