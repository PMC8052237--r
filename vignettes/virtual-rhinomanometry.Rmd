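---
title: "Virtual rhinomanometry: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual rhinomanometry: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Active anterior rhinomanometry (AAR) measures the pressure difference
between the nasal entrance (ambient) and the nasopharynx against the
airflow through one nostril, one side at a time, while the subject
breathes.  Computed-tomography-based flow simulation promises the same
pressure-flow relation without the measurement session: segment the
nasal air space from the CT, impose a flow rate, solve for the pressure
field, read off the pressure drop.  Whether the two methods *agree* is a
method-comparison question: paired values, log-scale Bland-Altman
limits, correlations adjusted for the factors (subject, side,
respiration phase) that trivially inflate them.

`rhinoflow` implements that comparison pipeline end to end and, because
clinical CT and rhinomanometry data cannot ship with a package, pairs it
with a synthetic-data stage that emulates the geometric and statistical
structure of the real inputs: voxel phantoms with nasal-like bent
channels, and Rohrer-model pressure-flow generators for clinical curves
(including their rendered-plot form, for the digitizer).

## Pipeline stages

1. **Phantom / volume input** (`phantom_spec()`, `build_phantom()`,
   `read_volume_nifti()`): a Hounsfield-unit voxel grid.
2. **Air-space extraction** (`threshold_air()`, `detect_tip()`,
   `place_probes()`, `grow_airway()`, `block_nostril()`).
3. **Flow solution** (`lattice_config()`, `run_to_stationary()`): D3Q19
   lattice Boltzmann, BGK collision, optional Smagorinsky closure.
4. **Curve assembly** (`build_sim_curve()`, `bin_curve()`,
   `drop_nearzero()`, `resistance150()`, `choose_clinical_state()`).
5. **Plot digitization** (`render_aar_plot()`, `mask_color()`,
   `discretize_mask()`, `calibrate_points()`).
6. **Agreement statistics** (`logdiff()`, `bland_altman()`,
   `adjusted_correlation()`, `pearson_corr()`, `paired_ttest()`).
7. **Orchestration** (`run_config()`, `run_pipeline()`), plus a thin
   command-line front end in `inst/cli/rhinoflow.R`.

## Segmentation model

Air is every voxel at or below **-460 HU**; the boundary is inclusive (a
voxel at exactly -460 HU is air) so the rule is deterministic and
testable.  The nasal tip is the first tissue voxel, scanning anterior to
posterior, that touches air within a central band of the left-right axis
(band half-width 25% of the axis by default); ties break towards the
midline, then superior.  This scan is one concrete realization of
"automatic tip detection" and is exposed as a configurable rule.

Two probe regions anchor the simulation: a sphere centered at the tip
(patient scale 70 mm diameter) whose surface carries the ambient
pressure boundary, and a cuboid (patient scale 60 x 40 x 30 mm) placed
on the oropharynx, realized here as the centroid of the most inferior
connected air slab posterior to the channel junction.  Region growing
keeps the 26-connected air component seeded inside the cuboid;
26-connectivity avoids spurious disconnections in thin passages, the
known failure mode of threshold segmentation in narrow meatus.  Exterior
air *outside* the sphere is excluded from growth (a flood fill from the
anterior volume face restricted to outside-sphere voxels), so the grown
domain is exactly the nasal lumen plus the exterior air inside the
sphere, and the fluid voxels bordering the removed exterior form the
sphere-surface inlet.  For this construction to be well defined the
sphere must fully enclose both nostril apertures — with a part-covered
aperture the exterior fill leaks into the lumen.  At patient scale the
70 mm sphere does this by a wide margin; `phantom_probe_defaults()`
computes the smallest enclosing sphere from the phantom layout (about
three nostril diameters).

Nostril blocking, manual in a clinical workflow, is algorithmic here: a
plug of configurable depth (default 3 voxels along the
anterior-posterior axis) converts the side's aperture air — the air on
that side in the first mostly-tissue slabs — to wall, and connectivity
from sphere to cuboid is re-checked.  A user-supplied plug mask
overrides the automatic rule.

## The flow solver

The solver is a desk-scale D3Q19 lattice Boltzmann code:
single-relaxation-time BGK collision, half-way bounce-back walls, and an
optional Smagorinsky large-eddy closure
(`tau_eff = (sqrt(tau^2 + 18*sqrt(2)*Cs^2*|Pi|/rho) + tau)/2` on the
non-equilibrium stress norm `|Pi|`).  Air is held at 20 C (kinematic
viscosity 1.516e-5 m^2/s, density 1.204 kg/m^3); temperature-dependent
property changes during breathing are deliberately not modeled.

**Boundary conditions.**  The cuboid's most inferior fluid layer is the
outlet: each outlet cell is forced to the equilibrium distribution at
the plug velocity `Q / (open outlet area)`, with its *density taken
from its fluid-side neighbor* and the applied velocity governed by a
*flux controller*.  Both refinements matter.  An equilibrium velocity
cell pinned to the reference density fights the local suction pressure
and the flow stalls far short of the target flux (we measured 6% of the
prescribed flow on an early phantom); letting the boundary density
float with the adjacent fluid removes that conflict.  Even then the
cap's throughput is direction-dependent (about 84% of the nominal plug
flux under suction and 96% under injection on the duct), so the applied
boundary velocity is rescaled every monitoring interval until the mass
actually removed (or injected) per step matches the prescribed flow;
after the controller locks, inspiration and expiration pressure drops
mirror each other to a tenth of a percent on a straight duct.
Sphere-surface cells are equilibrium pressure cells: reference density,
local velocity.  Expiration flips the outlet velocity sign.

**Stationarity.**  Runs start from rest (or from the previous flow's
state, see below) and stop when the sphere-cuboid pressure drop is
stationary: peak-to-peak fluctuation over a 500-step window below +/-3%
of its running mean.  The fluctuation metric is peak-to-peak over a
sliding window — one concrete reading of a "+/-3% fluctuation" rule —
and an absolute floor (0.02 Pa) covers zero-flow runs where the
relative criterion is meaningless.  Non-convergence is flagged on the
result, not raised; flagged points are excluded from binning with a
warning.

**Units and the automatic time step.**  With grid spacing `dx` and time
step `dt`, `u_lat = u dt/dx`, `nu_lat = nu dt/dx^2`,
`tau = 3 nu_lat + 0.5`, and pressure converts back through
`p = (rho_lat - 1)/3 * rho * (dx/dt)^2`.  One time step serves a whole
flow sweep; it is chosen so the peak lattice velocity in the narrowest
open cross-section stays near 0.025.  This target is a compressibility
compromise: the lattice pressure deviation scales with `dt^2`, and at
0.05 we measured 16% density deviations (and correspondingly distorted
fluxes) on constricted phantoms, while 0.025 keeps them under ~5%
without pushing `tau` into the unstable region just above 0.5.  `tau`
below 0.505 without the LES closure raises an error.  Warm starts
(re-using the distribution state of the previous flow in the sweep) cut
most runs to a few hundred steps.

**Verification.**  On a staircased circular duct the solver matches the
Hagen-Poiseuille pressure gradient to within a couple of percent at 8-
and 16-voxel radii (Reynolds below 100, probes in the developed region,
measured flux in the analytic formula).  The voxelization includes cells whose center
lies within the nominal radius; we measured the effective hydraulic
radius of that rule to be within about 1% of nominal, whereas carving at
`R - 0.5` (the naive half-link offset) leaves an effective radius near
`R - 0.5` and 4th-power errors of 13-34%.  Grid halving (8- vs 16-voxel radius at matched Reynolds, diffusive
scaling) moves the nondimensional result by about one percent; very
coarse cylinders (6 voxels) additionally show a staircase-parity wobble
of the effective radius, which is why the refinement pair starts at 8.  Mass in closed domains is conserved to accumulation error,
and the zero-velocity equilibrium is an exact fixed point.

## Desk-scale similarity: flow and pressure scaling

A 64^3 phantom at 0.4 mm spacing is a few-centimetre "nose" whose
channels would choke at clinical flows.  Sweeps therefore run at
`flow_scale` times the nominal flow (default 0.001, peak channel
Reynolds ~25-30, laminar, LES off) and record
`pressure x 1/flow_scale`.  In the viscous regime the pressure drop is
proportional to the flow, so the recorded value is the pressure the same
geometry would produce at the nominal flow — the standard low-Reynolds
model-scaling argument.  The recorded curves are then directly
comparable with clinical-scale Rohrer curves.  What this deliberately
does not emulate: the quadratic (inertial) share of clinical nasal
pressure drops, turbulence above ~290 ml/s, and mucosal compliance.
Passing tests on phantoms therefore validate the pipeline's mechanics
and bookkeeping, not patient-scale aerodynamics.

## The synthetic cohort

The default study is five phantom subjects: four with a right-sided
constriction and one left-sided (mirroring a typical septoplasty
cohort's deviation pattern), constriction factors 0.84-0.92, seeded
centerline jitter.  The shared channel radius (1.2 mm) was sized once
so that every side's unilateral resistance falls between roughly 0.5 and
1.0 sPa/ml (measured 0.64-0.87 across the ten sides).  That window is
the clinically sensible one for this sweep design: below 0.5 sPa/ml the
50 ml/s bin falls inside the +/-25 Pa exclusion band, and above ~1.2 the
25-point sweep can step over the 125-175 Pa resistance band entirely.
Real noses sit in the same range.

Synthetic clinical curves come from the Rohrer law
`dp = k1 Q + k2 Q |Q|` — the classical empirical pressure-flow form for
airway resistance; the clinical curves' true functional form is not
published, so this is a modeling choice of the generator, not a claim
about the source data.  Per side, coefficients are fitted to the
simulated sweep and scaled by mucosal-state gains (congested 1.4x,
decongested 0.95x — the CT is taken in whatever state the nasal cycle
left the mucosa, so one state should sit near the simulation), with
5 Pa Gaussian pressure noise on top; flow is the controlled variable.
The recording emulator adds what plotted clinical traces actually show:
three breathing cycles, a 6% per-cycle gain drift, and a pressure phase
lag of 0.07 cycles that opens the familiar inspiration/expiration loop.
Those four defaults were chosen to reproduce the reference digitization
density (more than 1500 points per curve from an 847 x 757 raster with a
5 x 5 window) with margin across seeds.

## Curve analysis rules

* **Binning**: flows group into 50 ml/s bins around 0, +/-50, ...; bins
  are half-open `[c - 25, c + 25)` so a boundary value joins the upper
  bin (closed-sounding ranges would overlap at the edges).  Pressures
  aggregate as per-bin means; absolute values are taken after
  aggregation.
* **Near-zero exclusion**: bins with aggregated pressure in (-25, 25) Pa
  are removed — around zero the respiration phase is ambiguous.  On a
  0-600-by-50 sweep this removes exactly the zero-flow bin, leaving 24
  retained bins per side.
* **Resistance at 150 Pa**: points with |dp| in [125, 175] Pa are
  labelled 150 Pa; their absolute flows are averaged and resistance is
  `150 / mean flow` (sPa/ml), inspiration only.  The labelled numerator
  follows the evaluation convention ("resistance at 150 Pa"); dividing
  by the actual mean pressure instead is available via
  `numerator = "actual"`.
* **Clinical state choice**: of the congested and decongested binned
  curves, the one with the smaller mean absolute log10 pressure ratio to
  the simulated curve over their common bins is the clinical curve; ties
  go to congested and are messaged.  The mean-absolute-log-ratio metric
  is this package's concrete reading of "better matching".

## Agreement statistics

All comparisons run on log10 values, where a difference is the log of
the clinical/simulated ratio.  `bland_altman()` reports, per stratum
(side x phase for pressures; one unilateral-inspiration stratum for
resistances), the mean log difference and a dispersion half-width of
`1.96 x sd`, both back-transformed to ratio factors (`10^x`).  The 1.96
multiplier is the limits-of-agreement convention; dispersion bands of
the width this analysis produces at n ~ 50 are far too wide to be
standard errors of the mean, so the half-width is interpreted as a
limits-type interval and the multiplier is configurable.
`adjusted_correlation()` residualizes both log columns on additive
indicator models of subject, side and phase and correlates the
residuals — a partial correlation that removes the variance those
factors would otherwise contribute; its p-value uses the t transform
with `n - rank - 1` degrees of freedom.  `pearson_corr()` adds the
conventional strength categories (boundaries assigned upward: r = 0.8
is "strong", r = 0.6 "moderate").  `paired_ttest()` handles the
degenerate cases explicitly (identical vectors: t = 0, p = 1; constant
non-zero differences: infinite t with a warning).  p-values are
two-sided throughout and no multiple-testing correction is applied.

## Problem sizes and reproducibility

The shipped study conditions are sized for a single CPU: 64^3 phantoms
(about 12k fluid cells), 25-condition sweeps per side with warm starts,
6- and 12-voxel-radius duct benchmarks.  A five-subject study runs in a
few minutes; `scripts/acceptance.R` re-derives every headline quantity
from scratch.  All randomness (phantom jitter, Rohrer noise, recording
drift) flows from a single seed; solver runs are deterministic, so a
repeated run with the same configuration and seed is bit-identical.

## Known limitations

* Volume I/O is NIfTI; DICOM series must be converted upstream.
* The solver is isothermal, incompressible-limit, BGK-only; no MRT or
  thermal models, no turbulent-spectrum diagnostics.  Patient-resolution
  grids (0.234 mm / 1.8e-6 s with LES) are expressible in
  `paper_scale_config()` but are cluster/GPU territory, not desk runs.
* The equilibrium-type boundaries trade accuracy for robustness; the
  pinned-density pressure layer inside the cuboid biases the oropharynx
  mean slightly towards ambient.
* Phantoms are smooth swept tubes: no turbinates, no CT noise or
  beam-hardening, no paranasal sinuses; segmentation edge cases beyond
  narrow-passage connectivity are not exercised.
* The digitizer assumes affine axes and hard-edged colors;
  anti-aliased pixels fall outside the +/-10 tolerance and are dropped
  by design.  PDF parsing is out of scope (rasterize first).
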