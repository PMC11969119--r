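---
title: "carotidflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carotidflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`carotidflow` simulates pulsatile blood flow through idealized planar
carotid bifurcations and quantifies the wall-shear environment that drives
atherosclerotic plaque formation and vulnerability. This vignette is the
package's methods account: the governing models, every tunable parameter
that matters, the numerical choices, and the design decisions taken where
the problem was genuinely open.

## The physical problem

The common carotid artery (CCA) splits into the internal carotid (ICA,
feeding the brain, with a widened carotid bulb at its origin) and the
external carotid (ECA). The flow divider ("bifurcation ridge") is an
impingement zone with elevated pressure and wall shear stress (WSS), while
the outer walls of the bulb and branches develop slow, recirculating,
low-shear flow. Low and oscillatory WSS promotes atherogenesis; high WSS at
plaque shoulders promotes rupture. The package asks two questions at desk
scale: how does plaque *placement* (configurations A1–A5: combinations of
ridge, outer-ICA and outer-ECA plaques) reshape the hemodynamic
environment, and how does the ICA–ECA *bifurcation angle* (25°–45°) modulate
velocities and WSS extremes?

## Geometry: a parametric 2D planar analog

The geometry module is the package's synthetic-data generator. Instead of
image-derived 3D lumens it builds a two-dimensional planar channel network
whose widths follow the nominal vessel dimensions (CCA diameter 6.35 mm and
length 32 mm; ICA distal width 4.5 mm, length 23.09 mm; ECA distal width
3 mm, length 19.35 mm):

* **Trunk and branches.** The CCA runs along +x; at the junction the lumen
  splits around a flow divider into an upward-deflected ICA and a
  downward-deflected ECA. All walls are x-monotone curves, so every cross
  section is a vertical segment — this is what makes the fully structured
  meshing and fast point location below possible. Branch widths (measured
  perpendicular to the branch centerline) taper linearly from their share
  of the junction section to the distal values.
* **Angle convention.** `bifurcation_angle` is the *total* ICA–ECA angle.
  The ICA takes `angle_split` (default 2/3) of it, reflecting the larger
  ICA deflection seen in carotid anatomy; both readings of the angle
  (per-branch vs total) are reachable through `angle_split`.
* **Junction split.** The junction section is divided so the proximal
  perpendicular branch widths are in the ratio of the distal diameters
  (ICA:ECA = 4.5:3). With equal branch dimensions, equal angles and no
  bulb the construction is exactly mirror-symmetric (a tested invariant).
* **Carotid bulb.** No bulb dimension is tabulated anywhere, so the bulb is
  a smooth outward widening of the ICA outer wall over the first third of
  the branch with apex diameter `bulb_diameter_factor` (default 1.3) times
  the proximal ICA width. A bulb is required for the outer-wall
  low-velocity zone to form at all.
* **Plaques.** A plaque is an inward squared-sine bump: zero thickness and
  slope at both shoulders, apex thickness twice the stated mean so the
  along-length average equals the tabulated "average thickness" (CCA/ridge
  7 mm × 1 mm, ICA 5.12 mm × 2 mm, ECA 4 mm × 2 mm). A *ridge* plaque is
  one plaque draped over the divider wedge: each face carries half the
  mean (apex protrusion per face = the stated mean); applying the full
  mean to both faces would double the obstruction of a single plaque and
  nearly occlude the ECA. The ICA plaque sits in the bulb/carotid sinus,
  the anatomical predilection site. Because the nominal thicknesses come
  from thicker 3D vessels, outer-wall plaque thickness is capped at
  `plaque_obstruction_cap` (default 0.6) times the local plaque-free
  half-width — without the cap a 2 mm-mean (4 mm apex) plaque simply
  exceeds the planar ECA lumen; any applied cap is recorded in the
  outline's `plaque_caps`. With the cap disabled (`Inf`), outline
  construction fails loudly, naming the offending site, if a plaque would
  close a lumen below 5% of the branch width.
* **Blunt divider tip.** Real flow dividers are rounded; a mathematically
  sharp wedge also makes the apex WSS singular. The wedge therefore starts
  from a flat face of width `ridge_tip_width` (default 0.3 mm). The two
  corners of that face still concentrate stress — see the verification
  section for how the monitoring window avoids them.
* **Site windows.** Four wall windows are tagged following the standard
  figure annotation: **M** on the outer CCA wall just proximal to the
  branch take-off, **N** on the ICA outer wall at the plaque's upstream
  shoulder (or the bulb apex when no ICA plaque exists), **O** at the
  divider tip and its immediate flanks, **P** on the outer ECA wall
  opposite the flow divider. Window extents are about 1.5 local widths.

What the generator does *not* emulate: out-of-plane curvature, secondary
(Dean) vortices, elliptical lumens, wall compliance, and — critically — the
quadratic scaling of cross-sectional area with diameter. In a plane,
"area" grows linearly with width, so velocity drops across the bifurcation
are far smaller than in 3D; see Limitations.

## Fluid model and boundary conditions

Blood: incompressible, density 1060 kg/m³, laminar. Rheology is
Carreau–Yasuda by default,
μ(γ̇) = μ∞ + (μ0 − μ∞)[1 + (λγ̇)^a]^((n−1)/a), with μ∞ = 3.45 mPa·s,
μ0 = 56 mPa·s, λ = 3.313 s. The exponents are not tabulated in the source
material, so the standard blood values n = 0.3568 and a = 2 are the
defaults (a = 2 reduces the law to the Carreau model); both are
configurable. A Newtonian mode (μ = 3.5 mPa·s, admissible 3–4 mPa·s) backs
the analytic validations and the dimensionless numbers.

The inlet waveform is the printed cardiac pulse
u_m(t) = 0.5·sin(4πt + 0.0160236) m/s for 0 ≤ t ≤ 0.218 s, then a 0.1 m/s
diastolic plateau to t = 1 s. It is interpreted as the *cross-section
mean* velocity (the profile is not stated; a parabolic profile is imposed,
with a plug option), which makes the peak CCA Reynolds number
ρ·0.5·d/μ ≈ 962, consistent with the laminar bound. The raw waveform jumps
at the systole/plateau joints; a 10 ms cosine blend (configurable, exact
mode available) removes the jumps while preserving the cycle integral to
<1%. The inlet-velocity sweep (0.3–0.7 m/s) rescales the waveform so its
peak equals the requested value.

Both outlets carry the same 13,332 Pa pressure; since only pressure
*differences* drive incompressible flow, the solver applies traction-free
outlets and adds the 13,332 Pa gauge to the reported pressure field.
Walls are rigid and no-slip.

Dimensionless diagnostics: Womersley α = (d/2)√(2πρ/Tμ) (≈4.2 for the CCA
at μ = 3.8 mPa·s), Reynolds ρud/μ per branch, Dean number Re√(d/2Rc), and
vortex formation time VFT = ∫u_m dt / d (≈24.4 per cycle for the default
waveform). Neither a VFT definition nor the Dean curvature radius is given
in the source; the conventions used are the stroke-length integral above
and the branch take-off fillet arc radius, and both are documented as
conventions, not inferences.

## Solver

Equal-order P1–P1 finite elements on the triangulated lumen with SUPG/PSPG
stabilization (streamline-upwind momentum, pressure-stabilized
continuity), the viscous term in stress-divergence form with the
element-wise Carreau–Yasuda viscosity, and backward-Euler time stepping.
Advection velocity, viscosity and the stabilization parameter are
Picard-lagged and refreshed every `refresh_every` (default 5) steps, so
the sparse LU factorization is reused in between. The steady solver is the
same spatial operator under Picard iteration with under-relaxation (0.7)
and automatic inflow continuation above Re ≈ 400.

Properties worth noting:

* **Exact global mass balance.** Summing the (never-constrained)
  continuity rows with a constant test function cancels the PSPG terms
  element-wise, so inlet and outlet fluxes balance to linear-solver
  precision at every step — the instantaneous mass defect in practice is
  ~1e-12 relative.
* **Initial condition and cycle convergence.** Runs start from rest; the
  march stops when consecutive cycles differ by less than
  `cycle_convergence_tol` (default 1%) in relative L2, with a cap of
  `n_cycles` (default 3; the baseline converges to ~1e-6 by cycle 3).
  Results are reported on the final cycle, stored at 100 uniform instants.
* **Outlet artifacts.** The traction-free outlet with the stress-form
  viscous term perturbs the velocity profile within a few elements of each
  outlet (it enforces zero tangential traction there). All metric windows
  are interior, so this is cosmetic.
* **Verification.** Steady plane Poiseuille flow is reproduced to ~1% in
  centerline velocity and ~1.3% in wall shear; the oscillatory (Womersley)
  channel solution at α = 4.2 is matched to <3% RMS; a mirror-symmetric
  bifurcation splits flow 50/50 to <1%.

Default resolutions (the package's study configuration): characteristic
mesh size 0.6 mm with 5 geometrically graded boundary layers
(growth 1.3, first layer ≈ 0.1 mm), time step 2 ms, 3 cycles. A baseline
pulsatile run is ≈2500 nodes and takes about 1.5 minutes on one core.

## Wall metrics and risk stratification

Wall shear stress is recovered at every wall node by a one-sided quadratic
fit of the tangential velocity through the two nearest boundary-layer
nodes along the wall normal (second-order; exact for a parabolic profile),
with the wall viscosity evaluated from the recovered shear rate. In 2D the
WSS is a signed scalar (positive = proximal→distal drag). Cycle metrics
use the standard definitions — TAWSS = (1/T)∫|τ|dt,
OSI = ½(1 − |∫τ dt| / ∫|τ|dt), ECAP = OSI/TAWSS — none of which are
written out in the source, and uniform cyclic sampling (so the integrals
reduce to means). Degenerate no-flow walls get OSI = ECAP = 0.

Risk tiers follow the printed thresholds: high (TAWSS < 0.5 Pa with
OSI > 0.3, or ECAP > 1.5), medium (TAWSS 0.5–1.5 Pa with OSI 0.1–0.3), low
(TAWSS > 1.5 Pa with OSI < 0.1). These bands neither partition nor nest,
so the classifier applies them in the precedence HIGH → LOW → MEDIUM →
UNCLASSIFIED and records which criteria fired, so any other precedence can
be recomputed from stored metrics. ECAP's threshold is treated as
1.5 Pa⁻¹ (no units are printed for it).

Section profiles are sampled on vertical lines: B-B mid-CCA (0.7 of the
trunk length) and C-C across the proximal ICA at the bulb apex station,
by default at the peak-systole stored instant (argmax of the inlet
waveform).

## Particle transport

The platelet surrogate is a 3 μm sphere at blood density (no density is
stated; neutral buoyancy is the natural default and is configurable).
Its Stokes response time ρd²/18μ ≈ 1.5e-7 s, so TRACER and STOKES_DRAG
modes differ negligibly — both are provided, the drag update via an
exponential integrator. Transport is one-way coupled (platelet volume
fraction ≪ 1).

Release protocol (a documented convention): positions across the inlet
with density proportional to the local axial velocity and release times
over one cycle with density proportional to the instantaneous flow rate —
i.e., seeding proportional to flux in space and time. Integration is RK2
through the cyclically replayed stored cycle with a step bounded by half
the mesh size over the peak speed. Particles cannot cross walls: positions
are clamped reflectively into the lumen (no adhesion model; the near-wall
residence is logged instead). Each particle ends at an outlet or is
censored as RETAINED at `max_transit_cycles` (default 10) cycles, carrying
the censoring horizon as its residence time. The stagnation map
accumulates the time particles spend within a near-wall band (10% of the
local width) at speeds below 5% of the cycle-mean inlet speed, binned
along x per wall.

One contradiction in the source material is surfaced rather than
resolved: its Results state that more cells enter the ICA than the ECA,
while its Discussion claims greater accumulation in the ECA. The package's
tested property follows the Results statement (and the simulated flux
split, ~70/30 toward the ICA, agrees with it).

## Statistics

The source names no tests, so the package commits to: Spearman rank
correlation (average ranks on ties) with a Fisher-transform 95% CI using
the Fieller–Hartley–Pearson variance 1.06/(n−3) for angle trends;
Kruskal–Wallis omnibus plus Holm-adjusted pairwise Wilcoxon rank-sum tests
for site comparisons, with group medians reported for direction. The
sampling unit for location tests is the wall-node metric value within a
site window; such values are spatially autocorrelated along a wall, so
p-values are descriptive — the report prints this caveat. Underpowered
inputs (fewer than 2 groups of 3) return an explicit marker, never a
fabricated p-value.

## Verification study and the ridge monitor

Mesh independence is assessed on the quantity the field actually cares
about: the peak WSS on the flanks of the flow divider. Two numerical
facts shape the monitor:

1. The blunt-tip corners are genuine stress singularities of the planar
   idealization; WSS sampled ever closer to them grows without bound under
   refinement. The flank window therefore spans arclengths 0.5–1.5 mean
   proximal branch widths from the apex — the regular region where the
   elevated divider shear lives, clear of the corner artifact.
2. Node-based sampling moves the evaluation points with the mesh. For the
   refinement study the WSS is instead rebuilt at *fixed* arclength
   stations from velocities interpolated at fixed physical offsets
   (0.12/0.24 mm) along the wall normal, so successive meshes answer the
   same question.

The study configuration is three steady solves at sizes in ratio
2 : √2 : 1 with the finest at 0.424 mm, driven at the cycle-mean inlet
velocity (0.155 m/s). Observed behavior: ≈2% change between the two finest
levels and a fine-grid GCI (safety factor 1.25, Richardson extrapolation;
assumed order 2 when convergence is non-monotone, flagged as such) of
≈3%.

## Limitations

* **Planar area scaling.** The headline 3D observation that the ICA
  section maximum velocity falls ~80% below the CCA's cannot be reproduced
  in a planar analog: with widths in place of areas, the bulb widening and
  ~70/30 flow split leave the ICA jet within a few percent of the CCA
  maximum. The package computes and reports the quantity; its value is a
  property of the 2D idealization, and the discrepancy is expected, not a
  defect of the solver.
* **Outer-ECA shear.** At the smallest angle the planar model develops no
  separation pocket on the outer ECA wall, so window P is a moderate-shear
  zone here (the low-shear pocket forms on the bulb outer wall, window N,
  instead). Site values are reported as computed.
* No turbulence, no fluid–structure interaction, no adhesion kinetics, no
  Windkessel outlets; statistics on wall-node samples are descriptive.

## Reproducing the numbers

`scripts/acceptance.R` re-runs the whole chain — baseline pulsatile solve,
branch Reynolds numbers, section maxima, the three-level refinement study,
and the ridge-plaque (A5) run with its site-P TAWSS — and writes the
results as JSON. The testthat suite exercises every module against
closed-form oracles (Poiseuille, Womersley series, cycle-metric integrals,
flux-weighted seeding fractions) and the property invariants described
above.
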