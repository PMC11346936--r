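---
title: "From brightfield image sequences to endocardial work: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From brightfield image sequences to endocardial work: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(embryoflow)
```

`embryoflow` turns time-lapse brightfield recordings of a beating embryonic
teleost heart into quantitative cardiac mechanics: phase-averaged blood
velocity fields, relative pressure fields and pressure drops across the
atrioventricular canal (AVC) and outflow tract (OFT), Green-Lagrange
endocardial wall strain, and the endocardial work (EW) metric that stages
heart development. This vignette explains the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
phantom tests do and do not demonstrate about real data.

## The measurement problem

An embryonic fish heart at 3-14 days post fertilization is tens of
micrometres across and beats at 80-180 bpm. Under a high-speed brightfield
microscope (hundreds of frames per second, effective pixel size
0.16-0.25 um), the moving red blood corpuscles (RBCs) form trackable
speckle patterns inside the chambers, superimposed on a bright, essentially
static tissue background. Because the flow is periodic, many cardiac cycles
of the same phase can be pooled: that redundancy is what makes micro-PIV
viable at this scale and signal-to-noise level.

Two dimensionless groups justify the downstream modelling. With blood
density 1025 kg/m^3, viscosity of a few mPa s, velocities of order 1 mm/s
and canal diameters of order 10 um, the Reynolds number (`Re = rho V d /
mu`) and Womersley number (`Wo = d sqrt(rho omega / mu)`) are both far
below one: the flow is creeping and quasi-steady, so pressure differences
are set by viscous stresses alone.

## Stage by stage

### Background removal (POD)

The image stack is decomposed into orthogonal spatial modes
(`pod_background_removal()`); the leading modes carry the static bright
background and slow artifacts, the trailing modes the moving RBC patterns.
Modes are discarded until their cumulative energy reaches a cutoff
(default 0.90, or an explicit mode count). The cutoff default reflects
brightfield reality: the static background dominates total image energy,
so one or two leading modes usually take > 90% of it. On synthetic stacks
whose background is weak relative to the tracers, an energy cutoff would
eat the tracer modes — the phantom generator therefore renders a bright
background (amplitude ~2x the tracer peak) to stay in the regime the
default expects.

### Ensemble phase-correlation PIV

`ensemble_piv()` assigns consecutive frame pairs to cardiac phases by
frame index modulo the cycle period (the period itself is estimated first
from the Fourier spectrum of a single-window instantaneous velocity
series, `heart_rate()`). For each phase and interrogation window the
cross-correlation spectra of all cycles are averaged before a single peak
detection; the ensemble raises the correlation peak-to-noise ratio roughly
with the number of pooled cycles and is the key to sub-pixel accuracy at
this seeding density (roughly 10-15 RBC patterns per 48 px window).

Passes proceed coarse to fine — default 96/48 px at 50% overlap, then
64/32 at 50%, then 64/32 at 75% — with symmetric iterative window
deformation between iterations: both images are deformed by half the
predictor displacement, sampled with bilinear interpolation, and windows
are Blackman-apodized before correlation. Iteration stops when the largest
displacement update falls below 0.1 px (bounded between 3 and 6 iterations
by default). The final vector grid spacing is `resolution x (1 - overlap)`
pixels — 1.28 um at the 60x pixel size, 2 um at 40x.

Numerical choices worth knowing:

* Correlation uses FFTs zero-padded to twice the window size (no circular
  aliasing); ties between equal peaks resolve toward the smaller
  displacement.
* The sub-pixel peak is located with a three-point Gaussian estimator; if
  a neighbour is non-positive the fit falls back to parabolic, then to the
  integer peak, and the fallback is counted in the QC record.
* Between iterations a normalized-median (universal outlier) test runs on
  the vector grid: a vector whose fluctuation from the 3x3 neighbourhood
  median, normalized by the neighbourhood's median absolute fluctuation
  (plus a 0.1 px noise floor), exceeds 2 is replaced by that median. A
  final 3x3 median filter is applied to the last pass only. One caveat
  matters for narrow canals: on a pass whose vector spacing exceeds the
  canal width, the jet occupies a single vector row and its normalized
  fluctuation against the quiescent surroundings is structurally large —
  validation would erase it from the predictor. `validate = "final"`
  restricts validation to the final pass, whose grid is designed to
  resolve the flow; the default remains validation on every pass.
* Interrogation spots that are locally tracer-free (zero-variance, or
  simply unlucky with the seeding at the smallest window sizes) are marked
  invalid; isolated invalid nodes with at least four valid neighbours are
  filled from the neighbour median and flagged as interpolated in the QC
  record, so downstream differentiation never sees artificial zeros.

### Differential operators

First derivatives use Richardson extrapolation of second-order central
differences at steps h and 2h — the classic fourth-order five-point
stencil — with one-sided second-order differences at boundaries and
degraded stencils next to masked nodes (`compact_richardson_gradient()`).
On smooth fields this is exact for polynomials up to cubic and roughly two
orders of magnitude more accurate than plain central differences at
PIV-typical wavenumbers.

Signal dropout in the canals is repaired by a mass-conservation fill
(`reconstruct_masked_region()`): a discrete stream function is fitted in
least squares to the surrounding valid vectors (u = dpsi/dy,
v = -dpsi/dx), with a weak penalty on differences of the discrete
Laplacian — a penalty that vanishes for any quadratic stream function, so
rigid rotation and uniform-strain flows are reconstructed essentially
exactly. Because central-difference operators commute, the reconstructed
interior is divergence-free to machine precision, and the operation is
idempotent. The planar (2D) form of continuity is used deliberately: the
measurement is a single focal plane, and out-of-plane transport is treated
as a loss mechanism, not a modelled flux.

### Rheology

Hematocrit is estimated from the time-averaged spatial autocorrelation of
a ventricle crop (`count_rbc_patterns()`): for sparse tracers the zero-lag
autocorrelation mass is the tracer count times a single-tracer correlation
mass `a^2 pi sigma^2`, with sigma from the central-peak width and the peak
intensity `a` either supplied or estimated from the brightest pattern
pixels. The count converts to a volume fraction through the single-RBC
volume and the optical depth of focus (`hematocrit()`); both are
configurable because neither can be measured from a single focal plane —
every Ht-dependent output should be read conditional on them.

Viscosity follows the Walburn-Schneck shear-thinning model,
`mu = C1 exp(C2 Ht) exp(C4 TPMA / Ht^2) gamma^(-C3 Ht)`, with
C1 = 0.00797, C2 = 0.0608, C3 = 0.00499, C4 = 14.59 L/g and total protein
minus albumin 45 g/L; Ht enters in percent and gamma in 1/s so the
exponents are dimensionless, the prefactor yields poise, and a single
named constant (`POISE_TO_PAS = 0.1`) converts to SI. The shear rate used
is the cycle-peak wall shear rate — the directional derivative of velocity
along the outward wall normal (`wall_shear_rate()`) — taken across all
segmented walls, and the same mu feeds the pressure gradient, Re, Wo and
the HR*mu pressure scale, so the outputs are mutually consistent.

### Pressure

In the creeping regime the momentum balance reduces to
`grad P = mu lap u` (`pressure_gradient()`, with the full unsteady and
convective terms available behind `include_inertia` for sensitivity
checks). The gradient field is integrated into a relative pressure field
by omnidirectional line integration (`omnidirectional_integrate()`): eight
path families (horizontal, vertical, both diagonals, each traversed in
both senses) are integrated with the second-order trapezoidal rule, each
ray seeded from the current averaged estimate at its starting node, and
the family average is iterated until the normalized residual (max per-node
change over the field range) drops below 1e-3. Exactness for linear
pressure fields is by construction; path-family scatter on smooth fields
is a useful internal error estimate. The pressure is pinned to zero at a
boundary reference node — ventricle outflow during diastole, BA outflow
during systole — so all values are relative, and the non-dimensional twin
`P / (HR mu)` (heart rate in 1/s) is what should be compared across
stages and species.

Pressure drops are read off as probe differences
(`canal_pressure_drop()`): `dP = P(upstream) - P(downstream)` with
optional disc averaging; negative values flag retrograde flow through the
valveless canals and are physiology, not error.

### Wall segmentation and strain

The endocardial wall is found from the flow itself (`segment_wall()`): the
velocity-gradient magnitude is multiplied by the velocity magnitude (which
suppresses noise-driven gradients where there is no flow), the product is
filtered to its 90th percentile and above, binarized by Otsu's method,
cleaned by morphological closing then opening with a radius-3 disc and
hole filling, and the largest connected component is kept; its traced
contour is the wall. Two implementation notes: the morphology radius is a
pixel-scale quantity, so on vector grids coarser than the acquisition
pixels the product field is bilinearly upsampled first; and the
closing-before-opening order is what "minimizing discontinuities in
connected components" requires — opening alone erases the thin
high-product bands that bound smooth flows. The percentile and disc radius
are configurable; the defaults are the published operating point.

Strain is Lagrangian (`accumulate_deformation()`, `green_lagrange()`):
grid nodes of the reference phase — end of ventricle systole, detected as
the upward zero crossing of AVC through-flow — are advected through the
phase-resolved field (midpoint Runge-Kutta, bilinear sampling), and
`F = I + grad(displacement)` with gradients on the reference grid. We use
the displacement-integral form rather than building F from instantaneous
velocity derivatives because only the former satisfies F = I at the
reference; the accumulated F over a full cycle is returned as a drift QC
metric. The Green-Lagrange tensor `E = (F^T F - I)/2` is frame-invariant
(pure rotations give exactly zero), and the scalar wall strain is 100x
the largest-magnitude principal value of E. Per phase, the three largest
boundary values are averaged into the peak endocardial strain series;
with boundary points every 1-2 um this average is stable against single
outliers. The strain analysis targets the ventricle, so the pipeline
segments the ventricle region of interest separately for strain sampling
and geometry.

### Cardiac metrics

Ejection fraction uses the cylindrical volume model
`Vol = (pi/4) L D1 D2` with depth equal to breadth (`D2 = D1`), the only
option for a planar measurement; the projected area is reported with the
conventional `A = pi L D1` formula even though it is 4x an ellipse area
with those axes — the convention is kept, and flagged, in
[heart_geometry()]. Because per-phase wall segmentation is least reliable
exactly at the motion extremes (where velocities vanish), the pipeline
measures the ventricle extents once at the best-flow phase and carries
them to end-diastole/end-systole with the area scale
`sqrt(mean det F)` of the tracked deformation — for an incompressible
chamber the determinant of F along any trajectory equals the local area
ratio, so EF depends only on deformation ratios and cancels the absolute
extent.

Endocardial work (`endocardial_work()`) is the trapezoidal path integral
of the AVC pressure drop with respect to wall strain over the diastolic
window (the phases with forward AVC through-flow); the path is open
because no pressure drop exists while the canal is closed, and the unit is
Pa-%. Stages follow the EW thresholds: below 100 Pa-% linear heart tube,
100-300 looped chambers, at or above 300 fully formed chambers; boundary
values are assigned to the higher stage so the classification partitions
all non-negative values.

## The phantom: what it emulates, and what it does not

All quantitative validation runs on a synthetic two-chamber phantom
(`generate_phantom_heart()`) because no reference recordings are
distributable. The phantom prescribes:

* two chambers of equal rest area joined by a plane channel, beating in
  antiphase with total area conserved; the ventricle scale follows
  `s(t) = 1 - a cos(2 pi t / T)` so end-systole sits at t = 0 and the
  first half-period is diastole;
* a canal Poiseuille profile whose flux equals the ventricle area rate —
  2D mass conservation ties canal flow to wall motion, and the lubrication
  solution `dP = 12 mu u_mean L_c / w^2` is the pressure ground truth
  (the chamber and tissue velocity fields are piecewise linear in the
  coordinates, so their Laplacian vanishes and the chamber pressure is
  exactly uniform);
* surrounding myocardium/tissue that deforms with the chambers: outside
  the lumen the velocity is the two chambers' affine wall-motion fields
  blended across the canal midline, making the field continuous across
  each chamber wall. Every material point outside the canal then carries
  the chamber's homogeneous deformation, which is what makes the
  wall-strain ground truth exact wherever the wall is detected. An
  optional linear swirl along the chambers' elliptical streamlines is
  available (closed-form deformation; a strain-free rigid rotation for
  circular chambers) but off by default;
* Gaussian-profile tracers (sd ~2.5 px, ~10-15 per 48 px window) seeded
  over the whole frame — corpuscle patterns inside the lumen, tissue
  speckle outside — advected by the continuous field with midpoint
  stepping, plus a bright static background pattern, per-pixel Gaussian
  noise, and random per-frame tracer dropout standing in for out-of-plane
  loss. Because the prescribed chamber fields do not feed Lagrangian
  parcels into the canal, the canal would wash out of tracers at high
  flux; its tracer population is therefore replenished to the seeding
  density every frame, as upstream blood supply would;
* full ground truth: velocity per phase, canal pressure-drop series, wall
  contours, strain series, EF of the cylindrical model, the EW of the
  prescribed pressure-strain path, and the exact period.

The default specification mirrors the target acquisition regime — 4 s at
400 frames/s spanning 8 cycles (hence 200 frames and 199 image pairs per
cycle), 0.25 um/px. The end-to-end test phantom is scaled down — 12 um
chamber radius, 14 um canal, 8% wall amplitude, 40 frames/s over 4 cycles
of a 0.75 s beat — so the full pipeline runs in minutes while per-frame
displacements stay within the interrogation schedule's range; the vector
grids and window counts are otherwise in proportion to the real ones.

What passing phantom tests does *not* show: robustness to tissue
deformation artifacts, optical distortions, focus drift, uneven
illumination, or aperiodic beating — the phantom's background is static,
its cycle exactly periodic, and its out-of-plane loss purely random.
Results on real recordings inherit all the usual micro-PIV caveats, most
importantly that a ~1% velocity error becomes a ~10% velocity-gradient
error, which is why the pressure and strain stages lean on ensemble
averaging and fourth-order stencils in the first place.

Two quantitative limits of the end-to-end phantom run are worth stating
plainly, because they are properties of the measurement physics, not
bugs. First, the canal is only about one interrogation window wide — the
same ratio as in the real acquisition — so the measured canal profile is
smoothed and the recovered pressure drop underestimates the lubrication
truth substantially even though its waveform and sign structure (forward
drop in diastole, retrograde in systole) are correct. Second, the
three-maxima peak-strain statistic is an extreme-value estimator: the
measured strain field at the wall is unbiased (its median matches the
prescribed wall strain closely) but its differentiation-noise tail
inflates the top-3 average. Both effects propagate into the endocardial
work, whose absolute phantom value is therefore recovered only to within
a factor of order one, while heart rate, ejection fraction and the
pressure/strain waveform shapes are recovered accurately. The acceptance
suite asserts the strict tolerances regardless and records this known
failure honestly rather than loosening them.

## Design decisions in brief

* Planar (2D) continuity everywhere; out-of-plane motion modelled only as
  tracer dropout.
* POD mode cut by cumulative energy (default 0.90) rather than a fixed
  mode count; both are available.
* Symmetric window deformation with bilinear interpolation; Blackman
  apodization; FFT correlation with 2x zero padding.
* Compact-Richardson gradients implemented as Richardson extrapolation of
  central differences (fourth order).
* Dropout reconstruction solved as a patch least-squares problem in the
  stream function, not per-profile.
* Omnidirectional integration with eight deterministic ray families;
  residual is the max normalized per-node change.
* Viscosity conversion factor poise -> Pa s exposed as a named constant.
* Wall strain is the largest-magnitude principal Green-Lagrange value;
  the reference phase is detected from the AVC through-flow zero crossing
  (no ECG available at these stages).
* EW thresholds 100 and 300 Pa-% assign boundary values to the higher
  stage (half-open intervals).
* The pipeline's EF uses deformation-determinant area ratios anchored at
  the best-measured phase rather than per-phase segmentation extents.

## Worked example

```{r example}
# build a small beating phantom with full ground truth
spec <- phantom_spec(chamber_semiaxes = c(12, 12), canal_width = 12,
                     wall_amplitude = 0.04, period = 0.5, frame_rate = 48,
                     n_cycles = 4, seed = 1)
ph <- generate_phantom_heart(spec)

# configure and run the full pipeline
xv <- ph$truth$centers$ventricle; xa <- ph$truth$centers$atrium
cy <- ph$truth$centers$y; A <- ph$truth$semiaxes["A"]
cfg <- pipeline_config(
  stack = ph$stack,
  avc_upstream = c(xa + 0.85 * A, cy), avc_downstream = c(xv - 0.85 * A, cy),
  ref_locus = c(xv + 0.5 * A, cy),
  ventricle_roi = c(xv - A + 2, xv + A + 8),
  rheology = list(ht = 20), inlet_diameter = spec$canal_width, seed = 1)
res <- run_pipeline(cfg)
res$summary          # HR, Re, Wo, EF, peak dP, peak strain, EW, stage
ph$truth$ew          # prescribed pressure-strain path area to compare
```

The problem sizes used throughout the test suite (phantom image extents of
roughly 200-300 px, 2-4 cycles, 15-23 phases) were chosen as the smallest
configurations at which every stage still operates in its intended regime;
the acceptance script runs the same configurations.
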