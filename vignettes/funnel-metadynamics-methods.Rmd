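---
title: "Funnel metadynamics binding analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Funnel metadynamics binding analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelmeta)
```

`funnelmeta` implements, at desk scale, the computational machinery of a
funnel-metadynamics study of ligand binding to a nuclear-receptor
ligand-binding domain: the funnel restraint and its standard-state
correction, the two collective variables (a centre-of-mass distance and a
logistic native-contact count), well-tempered bias deposition, free-energy
surface reconstruction with basin and saddle detection, a
random-accelerated egress rule, and the conformational-ensemble analytics
(cross-correlation maps, contact occupancy, backbone helicity, RMSF
increments, anchor-residue distances) used to interpret the basins. The
full protein application requires cluster-scale solvated MD; every method
here is instead exercised, and validated, on analytic toy systems and
seeded synthetic ensembles whose ground truth is known exactly.

## The funnel restraint and the standard-state correction

A dissociating ligand explores an unbounded volume, which makes a binding
constant from a biased simulation ill-defined unless the unbound state is
confined. The funnel restraint solves this: a cone of half-aperture
$\alpha$ (measured from the axis) around the binding pocket merges into a
cylinder of radius $R_{\mathrm{cyl}}$ at axial distance $Z_{cc}$ from the
funnel origin. Inside the funnel the restraint does nothing; outside, a
one-sided harmonic wall $\tfrac{k_w}{2}(\rho - r(z))^2$ pushes back
(continuous, once differentiable). The geometry defaults are
$Z_{cc} = 0.5$ nm, $R_{\mathrm{cyl}} = 0.1$ nm, $\alpha = 1.1$ rad — the
protocol values of the published study this package operationalises. The
paper never states its wall force constant or its functional form; the
one-sided harmonic wall on the radial distance is this package's choice,
with a default stiffness of $10^4\,\mathrm{kJ\,mol^{-1}\,nm^{-2}}$, stiff
enough that an unbiased bound toy particle is outside the funnel in fewer
than 0.1% of recorded frames at 300 K.

With the unbound ligand confined to the cylinder, the binding constant
follows from the one-dimensional potential of mean force $W(z)$ along the
funnel axis:

$$K_b \;=\; \pi R_{\mathrm{cyl}}^2 \int_{\mathrm{site}}
  e^{-\beta\,(W(z) - W_{\mathrm{ref}})}\, dz ,
\qquad
\Delta G^0 = -k_BT \,\ln\!\left(K_b\, C^0 N_A\right),$$

with $W_{\mathrm{ref}}$ the mean of $W$ over a flat stretch of the
cylinder and $C^0 = 1$ M the standard concentration
($C^0 N_A = 0.6022\ \mathrm{nm^{-3}}$). `binding_delta_g()` implements
exactly this, reports $\Delta G$ in kcal/mol (conversion factor fixed at
4.184), warns when the chosen unbound window is not flat within
tolerance, and derives the dissociation constant through the package's
declared convention $K_d = C^0 \exp(\Delta G / RT)$. Published tables of
this kind are not always internally consistent under any single
conversion constant, which is why the convention is stated explicitly on
every result object rather than matched to any one table.

One practical subtlety: the correction uses the *nominal* cross-section
$\pi R_{\mathrm{cyl}}^2$, while a soft wall lets the particle penetrate a
distance $\sim\sqrt{k_BT/k_w}$, enlarging the effective section. At the
default stiffness and $R_{\mathrm{cyl}} = 0.1$ nm this biases $\Delta G$
by a few tenths of kJ/mol; the bundled 3-D binding fixture therefore uses
a stiffer wall ($2\times10^5\,\mathrm{kJ\,mol^{-1}\,nm^{-2}}$) so the
cylinder section is sharply defined, at the price of a smaller stable
timestep.

## Collective variables

CV1 is the mass-weighted centre-of-mass distance between ligand and
protein selections. CV2 is a smooth native-contact count: for a frozen
list of $m$ atom pairs defined once on a reference crystal structure,

$$S(X) = \sum_{i=1}^{m} \frac{1}{1 + e^{\beta (r_i - \lambda r_0)}},$$

with $\beta = 50\ \mathrm{nm^{-1}}$, $\lambda = 1.8$ and $r_0 = 0.45$ nm
by default. Each term is $1/2$ at $r = \lambda r_0$, saturates cleanly at
0 and 1 in floating point, and has an analytic gradient (used for biased
forces in the toy simulator). Pairs are identified between heavy atoms
only — the list is meant to come from a crystal structure, which has no
hydrogens — as every heavy-atom pair across a listed residue pair within
a 0.45 nm cutoff, ordered deterministically by serial number. Note the
deliberate asymmetry kept from the protocol: pairs are *identified* at
0.45 nm but the logistic midpoint sits at $\lambda r_0 = 0.81$ nm; the
package implements both numbers as given and does not reconcile them.

## The toy simulator

`langevin_metad_run()` integrates a single particle with the BAOAB
splitting of Langevin dynamics (chosen for its accurate configurational
sampling at practical timesteps) under a registered analytic potential,
the funnel wall, and the metadynamics bias. Units are
kJ/mol, nm, ps, amu. Randomness is drawn from R's generator, so
`set.seed()` makes runs bit-identical. A Gaussian hill is deposited every
`pace` steps with the well-tempered height
$w = w_0\, e^{-V(s)/((\gamma - 1) k_B T)}$; the accumulated bias and its
gradient live on a grid cache updated analytically per hill (multilinear
interpolation; the cache agrees with exact summation to well under
0.01 kJ/mol on the default grids — this is asserted by a test). The
protocol defaults carried in `default_config()` are the published ones:
height 1.0 kJ/mol, widths 0.1 (CV1) and 10 (CV2), a 2 ps pace,
bias factor 16.

Registered presets: an isotropic harmonic well; a tilted quartic double
well (barrier 20 kJ/mol, minima offset 3 kJ/mol by default); a smoothed
axial square well; a spherical trap inside a funnel (`funnel_trap_3d`,
the canonical end-to-end binding fixture); and a planar ring barrier with
a wide and a narrow gap for egress statistics. Every `make_toy()` call
returns quadrature ground truth alongside the system (basin $\Delta F$,
standard-state $\Delta G$, positional variance), computed from the same
energy callable the integrator uses, and rejects timesteps above
$0.5/\sqrt{k_{\max}/m}$ for the stiffest curvature $k_{\max}$ of the
chosen parameters.

The egress rule mirrors the random-accelerated protocol: a constant force
(default 16 kcal mol$^{-1}$ Å$^{-1}$) acts on the particle; every 100 fs
the displacement since the last checkpoint is compared with 0.025 Å, the
direction is kept only if the displacement *strictly* exceeds the
threshold (the equality case resamples — the strict reading of the rule),
and resampling is uniform on the sphere via a normalised Gaussian triple.

## Free-energy reconstruction and basins

The estimator is the standard well-tempered rescaling
$F(s) = -\tfrac{\gamma}{\gamma-1} V_{\mathrm{hills}}(s)$, zeroed at its
minimum. The late-time estimator oscillates with the still-arriving
hills, so `fes_tail_average()` averages reconstructions at several
checkpoints over the tail of the deposition history (default: eight
checkpoints over the last 30%); the binding fixtures additionally average
the profiles of several independent walkers. Two-CV surfaces are
projected to the axial coordinate by Boltzmann marginalisation
($-k_BT \ln \sum e^{-F/k_BT}$) before the funnel correction, since the
correction itself is one-dimensional.

Basins are local minima whose topographic persistence — depth below the
lowest saddle connecting them to deeper territory, computed by an
ascending flood with union–find merging (8-neighbourhood in 2-D) —
exceeds a threshold (default 2 kcal/mol, so only pronounced minima are
labelled). Minima sitting on the grid boundary are treated as domain
artefacts, not basins. Saddle points between basins are found by the same
flood: the cell whose addition first connects the two minima is the
minimax saddle (verified against brute-force path enumeration in the
tests). Each basin's extent is the bounding box of its steepest-descent
catchment at its iso-level, so extents never overlap; `assign_frames()`
labels CV records by extent, breaking hypothetical ties toward the deeper
basin and recording that it did so.

Convergence is monitored the way the original protocol describes:
`convergence_profile()` reports the maximum absolute change of the
reconstructed surface between successive time windows. Uncertainties are
block standard errors (`block_errors()`, five contiguous blocks by
default), which for correlated series exceed the naive iid error — also
asserted by a test.

## Ensemble analytics

All analytics consume a `labeled_ensemble` (shared atom table, frames,
optional weights). Superposition is the Kabsch SVD solution with the
reflection guard; ensembles are fitted to their mean by a two-pass
iterated mean fit. The cross-correlation map is computed on
C$\alpha$ atoms after that fit:
$\mathrm{DCC}_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$, with
zero-variance residues reported as missing rather than zero, and a 0.4
display threshold on the plot method (the customary presentation).
Contact occupancy is the weighted fraction of frames in which any
heavy-atom pair across two residues is within 0.45 nm. Helicity uses a
fully specified dihedral-window criterion — a residue is helical when
$\phi \in [-100^\circ, -30^\circ]$ and $\psi \in [-67^\circ, -7^\circ]$ —
rather than a secondary-structure program, keeping the criterion exact
and the package dependency-light. The fluctuation increment between a
mutant and a wild-type ensemble is the mean per-atom difference of summed
RMSF over a shared selection, in Å, sign preserved; distance statistics
over anchor residues use the population (not sample) standard deviation,
as figure annotations of this kind conventionally do.

## What the synthetic generators emulate — and what they do not

`make_ensemble()` plants each analytic's target signal orthogonally: an
ideal-helix backbone built from internal coordinates (NeRF placement,
ideal bond geometry) with per-residue helix/coil emission at stated
probabilities (helix $(\phi,\psi) = (-57^\circ,-47^\circ)$, coil
$(-120^\circ, +120^\circ)$, 5° jitter — unambiguous against the helicity
window); paired-residue translations with exact planted cross-correlation
$\rho$; Bernoulli-planted contacts placed well inside or well outside the
cutoff; and iid per-atom Gaussian noise whose expected RMSF is
$\sigma\sqrt{3}$. Every generator returns its *realised* draws as a
machine-readable truth record, and the tests compare estimators against
those records — never against hand-copied numbers. Estimator recovery is
therefore exact up to binomial sampling of the plant itself, which is the
scale the acceptance checks use.

What passing these tests shows is that the estimators are correct on data
whose generating process is known. What they cannot show is fidelity to
real protein ensembles: synthetic frames have no solvent, no force-field
anharmonicity, no coupling between helicity and contacts, and rigid
residues; the toy simulator has one particle, not $10^5$ atoms. The
published protein-scale numbers (binding tables, egress channel counts,
per-residue observables of the receptor) are therefore explicitly out of
desk-scale reach; the package carries the identical code paths validated
on the systems above.

## Problem sizes and numerical choices

The bundled study conditions, chosen once as realistic desk-scale
protocols and used unchanged by the tests and the acceptance script:

* double well: barrier 20 kJ/mol, asymmetry 3 kJ/mol, $10^6$ BAOAB steps
  at 5 fs, hills of 1.2 kJ/mol every 250 steps, $\gamma = 16$,
  $\sigma = 0.1$ nm. Basin $\Delta F$ lands within 1 kJ/mol of
  quadrature.
* funnel trap: well depth 25 kJ/mol, radius 0.25 nm, six independent
  walkers of $8\times10^6$ steps at 1 fs, hills of 1.5 kJ/mol every 250
  steps, $\gamma = 12$, tail-averaged from 70%, profiles averaged across
  walkers after aligning on the cylinder plateau. $\Delta G$ lands within
  5% (typically 1–2%) of direct partition-function quadrature.
* planted ensembles: 2000–5000 frames, matching the recovery tolerances
  (DCC $\pm 0.05$, $\Delta$RMSF 5%, binomial bands for fractions).

Other numerics worth knowing: hill evaluation truncates Gaussians at
$6\sigma$; grid flooding breaks value ties by cell index, making basin
and saddle output deterministic; `switching_value` saturates instead of
overflowing; degenerate (collinear) superposition fits are accepted
because the least-squares optimum is still attained, though the rotation
is then not unique; and `hills_from_fes()` — the inverse generator that
manufactures a hills log whose well-tempered sum reproduces a given
surface — reports its achieved residual and warns when the hill budget
was too small.

## Known limitations

* Only one- and two-dimensional CV grids; no reweighting of auxiliary
  observables by the bias (basin-conditional averages are used instead,
  mirroring the original analysis).
* The trajectory readers cover PDB/multi-model PDB and DCD (via bio3d);
  XTC is not readable with the available toolchain and raises a clear
  error.
* Funnel placement is user input; the package never infers the axis from
  a structure.
* The RAMD egress test is a radial shell around the funnel origin, not an
  arbitrary predicate.
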