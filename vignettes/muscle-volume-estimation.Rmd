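---
title: "Estimating muscle volume from ACSA profiles: methods and design"
author: "muscleVolume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle volume from ACSA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleVolume)
```

## The problem

Slice-by-slice segmentation of axial MRI is the reference method for
quantifying skeletal muscle volume (MV): outline the muscle on every
slice, multiply labelled-voxel counts by the voxel volume, and sum. It is
accurate but slow — hours per leg — which rules it out wherever results
are needed quickly (training monitoring, rehabilitation, large field
studies). Two shortcuts are in practical use for fusiform thigh muscles:

* **Shape-factor method.** MV is modelled as a fixed fraction of the
  bounding cylinder,
  $$p = \frac{MV_{\mathrm{ref}}}{L \times ACSA_{\max}}, \qquad
    \widehat{MV} = p_{\mathrm{avg}} \times L \times A(\bar{x}_{\max}),$$
  where $L$ is muscle length, $ACSA_{\max}$ the maximal anatomical
  cross-sectional area, and $p_{\mathrm{avg}}$ a cohort-average shape
  factor. In practice the subject's own peak is unknown, so the area
  $A(\bar{x}_{\max})$ is read at the *cohort-average* peak location
  $\bar{x}_{\max}$ — one slice to segment per muscle.
* **Truncated-cone (frustum) method.** Five cross-sections are segmented
  — at 1% and 100% of muscle length, at $\bar{x}_{\max}$, and halfway
  between $\bar{x}_{\max}$ and each end — and the volume is the sum of
  four conical frusta,
  $$\widehat{MV} = \sum_{i=1}^{4}
    \frac{d_i}{3}\left(A_i + A_{i+1} + \sqrt{A_i A_{i+1}}\right),$$
  with $d_i$ the inter-slice distances. The frustum quadrature is exact
  whenever the equivalent radius varies linearly between samples.

This package implements the full chain — per-slice ACSA extraction,
profile normalization to relative muscle length, peak localization, both
estimators, and Bland–Altman agreement against the slice-by-slice
reference — together with a voxelized phantom generator that supplies
exact ground truth, since real segmented cohorts are rarely shareable.

## From label map to profile

`sliceAreas()` decomposes a `LabelVolume` (a 3D integer label map with
anisotropic voxel spacing, read from NIfTI-1 via `readLabelVolume()`)
into per-slice areas: labelled-voxel count × in-plane voxel area.
Conventions, and why:

* **Relative length runs 0% = distal to 100% = proximal.** Both physical
  slice orders occur in practice; the `distalEnd` metadata on the volume
  triggers an internal flip, and all downstream quantities are invariant
  under flipping the slice axis together with that flag (tested).
* **Muscle length = occupied span × slice thickness.** Each slice stands
  for a full slab; this keeps length consistent with
  $MV = \sum_i A_i \, \Delta z$, which the package maintains as an exact
  identity (tested on random phantoms).
* **101-point grid, linear interpolation.** The profile holds one ACSA
  per 1% of muscle length. Slice centers map to $x_i = (i - 0.5)/N$ over
  the occupied span of $N$ slices; values on the 1% grid are linear
  interpolations, with constant extrapolation beyond the outermost slice
  centers. Nothing in the measured data motivates a higher-order
  interpolant, and a linear rule keeps the frustum estimator's inputs
  monotone between samples.
* **Peak localization.** `findAcsaMax()` takes the argmax on the 1%
  grid; exact ties (plateaus, e.g. a cylinder) resolve to the plateau
  midpoint rounded down to the grid — a deterministic,
  orientation-symmetric rule. Real profiles essentially never tie.
* **Degenerate inputs.** An absent label is an error; interior empty
  slices (axial segmentation holes) are retained with area 0 and
  produce a warning; a single-slice muscle has a length but no profile
  (resampling requires ≥ 2 slices).
* **Multiple in-plane components are summed** — the ACSA is the full
  labelled area of the slice.

## Estimators

`fitShapeFactorModel()` computes one $p$ per subject from that subject's
own reference volume, length and peak area ($0 < p \le 1$ always, since
$MV \le L \cdot ACSA_{\max}$), then stores the plain arithmetic mean
$p_{\mathrm{avg}}$, its SD, and the cohort-mean peak location. The
default is full-cohort averaging (self-estimation, appropriate when a
reference cohort doubles as the evaluation cohort); `leaveOneOut = TRUE`
excludes the target subject at estimation time, the honest choice for
out-of-sample claims — with n ≈ 39 the two differ negligibly.

`estimateShapeFactor()` is the in-practice variant by default: the area
is sampled at the cohort-average location, not at the subject's own
peak. `ideal = TRUE` substitutes the subject's own $ACSA_{\max}$, and
`pOverride` lets the caller insert a subject-specific $p$; with both,
the estimate inverts the definition of $p$ and reproduces the reference
volume to machine precision (tested). The gap between the practice and
ideal variants is exactly what drives the method's imprecision: when a
subject's true peak sits far from the cohort average, the sampled area
underestimates $ACSA_{\max}$ and the volume is underestimated.

`estimateTruncatedCone()` uses the frustum sum above with areas read
off the 101-point profile at full precision (positions are not snapped
to whole slices — the profile is already a 1% resampling). One
published formulation of the frustum sum omits the square root on the
cross term, which is dimensionally inconsistent (area + area²); this
package implements the standard conical-frustum quadrature with
$\sqrt{A_i A_{i+1}}$, as used throughout the truncated-cone literature,
and provides no as-printed variant. Two structural properties follow
and are tested: the estimate never exceeds $0.99 \, L \cdot ACSA_{\max}$
for unimodal profiles, and because a spindle carries mass near both ends
that the 1%/100% end-slices truncate and the concave mid-section is
under-quadratured, the method *systematically underestimates* — high
bias, but low between-subject spread, since the geometry driving the
bias is shared across subjects.

`blandAltman()` summarizes per-subject relative differences
$100\,(MV_{\mathrm{ref}} - \widehat{MV})/\text{mean of the two}$ (so
positive = underestimation) with bias, sample SD ($n-1$), and the
classical fixed limits of agreement at bias ± 1.96 SD. The
mean-of-methods denominator is the standard Bland–Altman choice for
ratio-scale data; `denominator = "reference"` is available, and with
differences around 10% the two conventions differ by under one point.
No regression-based limits and no confidence intervals on the limits
are provided.

## The phantom generator

Real thigh-muscle segmentations are not generally available, so
validation runs on voxelized phantoms with closed-form truth. Four
families: cylinder, cone (apex distal), frustum (linear radius), and the
**beta spindle**, the one meant to look like a muscle:
$$A(x) = A_{\max}\left(\frac{x}{x_m}\right)^{\alpha-1}
  \left(\frac{1-x}{1-x_m}\right)^{\beta-1},
  \quad \alpha = 1 + \kappa x_m,\; \beta = 1 + \kappa(1 - x_m),$$
a beta-function kernel rescaled so its mode sits exactly at the peak
location $x_m$ with value $A_{\max}$, tapering to zero at both ends.
Closed-form volumes are verified against adaptive quadrature of the area
profile to 1e-8 relative tolerance in the test suite.

Design choices, once and for all:

* **Sharpness default $\kappa = 3$.** The taper exponent is not
  identifiable from published summary statistics, so it was fixed on
  morphometric grounds: $\kappa = 3$ implies analytic shape factors of
  0.58–0.59 at thigh-muscle peak locations, inside the 0.55–0.65 band
  reported for quadriceps muscles in vivo. Spindle oracle tests use
  $\kappa = 2$ (the parabolic kernel $4x(1-x)$, $p = 2/3$) because its
  constants are exact by hand.
* **Elliptical cross-sections, aspect ratio 1.5.** Muscle bellies are
  not circular; semi-axes are solved from the area and the ratio, so the
  area profile — the only thing the method sees — is unchanged.
* **Center-inclusion voxelization.** A voxel is labelled iff its
  in-plane center lies inside the cross-section at its slice-center's
  axial coordinate: binary label maps behave this way, and the voxelized
  volume converges to the analytic volume under grid refinement
  (monotone over a three-step refinement in the tests).
* **Straight centerline, axis-aligned.** The per-slice method is
  centerline-agnostic, so modelling curvature would add voxelization
  machinery without changing what is being validated. Likewise out of
  scope: MRI intensities, partial-volume effects, and segmentation-error
  models — the phantoms validate the *estimators*, not the segmentation.
* **Cohort simulation.** `generateCohort()` draws per-subject length,
  peak ACSA and peak location from normal distributions (location
  truncated to [0.05, 0.95] to keep peaks off the muscle ends; length
  and area truncated to positive), holding family, $\kappa$ and aspect
  ratio fixed. All randomness flows from one integer seed; identical
  specs give bit-identical cohorts, and the caller's RNG state is
  restored. The stock simulated cohort mirrors a vastus-lateralis-like
  study population: n = 39, length 400 ± 25 mm, peak ACSA
  3200 ± 400 mm², peak location 61.0 ± 9.7% of length, voxels
  0.65 × 0.65 × 2.00 mm.

What passing tests on these phantoms *do not* show: robustness to
segmentation error, to curved or oblique muscles, or to real anatomical
shape families beyond the spindle's unimodal taper. They do show that
the arithmetic chain is exact where it should be exact, and that the
estimators' bias/precision behaviour on realistic geometry reproduces
the pattern observed in vivo.

## Problem sizes and numerical tolerances

Oracle phantoms are L = 300 mm at 0.65 × 0.65 × 2 mm (≈ 1M voxels,
sub-second); simulated cohorts are n = 39 at the same grid (≈ 2.5M
voxels/subject, a few seconds per cohort) — large enough that
voxelization noise sits well below the tolerances being asserted, small
enough to re-run casually. Closed-form identities are asserted near
machine precision (1e-12 relative); voxel-mediated constants at 1–2
percentage points; the frustum-exactness property at 0.5%, its
voxelization/interpolation error budget.

## A worked run

```{r run, eval = FALSE}
cfg <- list(
  input = list(simulate = list(
    n_subjects = 39, muscle = "VL",
    length_mean = 400, length_sd = 25,
    peak_acsa_mean = 3200, peak_acsa_sd = 400,
    location_mean = 0.6103, location_sd = 0.0965)),
  seed = 61,
  output = list(dir = "vl_run"))
res <- runPipeline(cfg)
res$agreement
```

On this cohort the shape-factor method shows the smaller bias with the
wider limits of agreement, and the truncated-cone method the larger
(positive) bias with much tighter limits — accuracy versus precision.
The same pipeline consumes segmented NIfTI files via
`input$files = list(dir = ..., labels = list("1" = "VL"))`, and
`inst/scripts/musclevol.R` wraps both entry points for shell use.

## Known limitations

* Length quantization: a muscle's length is measured in whole slices, so
  a 2 mm slice thickness bounds length accuracy at ± 1 slice; phantoms
  whose ends taper below one voxel of area lose those end slices.
* The peak location is reported on the 1% grid; sub-percent localization
  is not attempted (and not supported by 2 mm slices at typical muscle
  lengths).
* Between-muscle differences in taper asymmetry are representable
  (any $x_m$, $\kappa$) but the generator draws one muscle per run;
  multi-muscle label maps are supported on ingestion, not simulation.
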