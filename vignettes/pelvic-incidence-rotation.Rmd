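---
title: "Measuring pelvic incidence under pelvic rotation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pelvic incidence under pelvic rotation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvir)
```

## The problem

Pelvic incidence (PI) is defined in 3D — the angle between the perpendicular
to the S1 endplate at its midpoint and the segment from that midpoint to the
midpoint of the bicoxofemoral axis — but is measured on 2D lateral
radiographs. When the pelvis is rotated relative to the viewing plane, the
endplate line, its apparent perpendicular and the hip-axis midpoint all move
in the image, and the measured angle drifts away from the anatomical value.
`pelvir` reproduces this measurement chain end to end so that the drift can
be quantified exactly, on geometry whose ground truth is known.

## The model

### Canonical frame and the frame split of PI

All geometry lives in a canonical scan frame: origin at the hip-axis
midpoint, x anterior, y left, z superior, units mm, angles degrees. The
sagittal image plane at 0° is the x–z plane, so the "vertical" and
"horizontal" reference lines of a lateral view are the z and x axes.

A pelvis is posed by two angles whose sum is the anatomical PI:

* `ss_frame` — inclination of the S1 endplate from the transverse plane of
  the scan frame (the scan-frame analogue of sacral slope), in (0°, 90°);
* `pt_frame` — tilt of the endplate-centre → hip-axis line from the
  scan-frame vertical (the analogue of pelvic tilt), in [0°, 90°).

`pi_anat = ss_frame + pt_frame` holds by construction (the endplate
perpendicular makes angle `ss_frame` with the vertical on the other side of
it). The split is an explicit generator parameter because the *projected* PI
at a given rotation depends on the split, not just on PI: two pelves with
identical anatomical PI but different supine orientations drift at different
rates. No published per-patient split exists for the reference cohort, so
the cohort generator draws `pt_frame ~ Uniform[0°, 15°]`, which keeps
`ss_frame > pt_frame` for every anatomically plausible PI (≥ 30°). That
ordering is what fixes the observed trend directions (see below).

### Synthetic structures

Each pelvis consists of three labeled point clouds (default 500 points
each), emulating what CT segmentation delivers:

* **Femoral heads** — closed upper hemispheres of radius 23 mm centred at
  (0, ±90, 0) (head separation 180 mm). A fixed 20 % of the points lie
  exactly on the equatorial rim at uniform azimuths — the planar cut
  boundary that segmentation of a half-head produces; the rest are uniform
  on the open cap. The right head is the exact mirror image of the left
  across the sagittal plane before asymmetry and noise, so noiseless
  zero-asymmetry models are perfectly symmetric.
* **S1 endplate** — a planar elliptical patch, 45 mm anteroposterior by
  35 mm mediolateral, centred 95 mm posterior–superior of the hip-axis
  midpoint along the direction fixed by `pt_frame`, and inclined by
  `ss_frame`. The AP width is deliberately the major axis: the endplate fit
  recovers the AP direction as the maximal-variance in-plane principal
  direction, which is only well-defined when AP variance dominates.

Patch points are drawn uniformly but with 8-fold reflection symmetry: each
first-quadrant draw is emitted at (±u, ±v) and mirrored across the quadrant
diagonal. This leaves the uniform density intact while making the sample
centroid *exactly* the endplate centre and the sample covariance *exactly*
diagonal in the (AP, ML) axes, with AP/ML variance ratio exactly (45/35)².
Two consequences matter: the noiseless pipeline recovers the generating
geometry to machine precision (a plain random patch would leave O(width/√n)
centroid and axis errors, an order of magnitude above the 10⁻⁶° contracts
the tests enforce), and the fitted AP axis can never flip to the
mediolateral direction at small point counts.

Measurement noise is isotropic Gaussian per coordinate (default sd 0.5 mm,
a typical sub-voxel segmentation jitter). Geometry defaults (23 mm heads,
180 mm separation, 95 mm sacrum distance, 45 × 35 mm endplate) are adult
pelvis scale conventions, not claims. The generator does **not** model
staircase or partial-volume segmentation artifacts, cortical thickness,
endplate curvature, or osteophytes — a green test establishes correctness
of the measurement chain, not robustness to pathological segmentations.

### Landmark fitting

* **Head centres** — default: algebraic least-squares sphere (linearized
  normal equations), exact on noiseless spherical data and using every
  surface point. Alternative `three_point`: a deterministic surrogate of
  manual circle drawing — the lowest decile of points by z approximates the
  segmentation rim, and three of them at the 10/50/90 % quantile positions
  of their azimuth ordering define the circle. On noiseless data the rim is
  exact and both estimators agree to machine precision; the three-point
  mode exists to let users quantify the cost of the manual method under
  noise. There is no outlier rejection: inputs are assumed segmented.
* **Endplate** — principal component analysis of the patch: centroid centre,
  least-variance normal, maximal-variance AP direction, with fixed sign
  conventions (normal toward +z, tie +x; AP toward +x, tie +z) so angles
  are reproducible run to run. The "endplate midpoint" is the patch
  centroid; the midpoint of the AP extent is available as an option since
  manual endpoint choices are not reproducible.
* Derived points: hip-axis midpoint (midpoint of head centres) and the
  sacro-femoral midpoint (midpoint of endplate centre and hip-axis
  midpoint).

### Projection and the two rotation axes

The viewing plane at rotation θ has basis u1 = R·(1,0,0), u2 = R·(0,0,1)
with R a proper rotation by θ about z ("vertical" rotation, i.e. axial
pelvic rotation) or about x ("horizontal" rotation, i.e. coronal
obliquity). Projection is orthographic — the CAD screen-capture model —
so image coordinates are dot products with (u1, u2). Rotating the viewing
plane by +θ and rigidly rotating the pelvis by −θ are exact inverses; both
routes are exposed and tested for equivalence. Rotation about the
mediolateral axis is excluded on principle: it is an in-plane rotation of
an orthographic image and cannot change any projected angle.

The axis naming deserves a note, because lateral-radiograph conventions are
ambiguous about which anatomical axis "vertical/horizontal rotation"
denotes. This package assigns vertical → superoinferior axis and
horizontal → anteroposterior axis. Under the idealized model this
assignment — and only this assignment — makes projected PI increase with
vertical rotation and decrease with horizontal rotation whenever
`ss_frame > pt_frame`, matching the published trend directions and the
reported agreement with an earlier phantom study of axial rotation. The
plane normal is oriented as u2 × u1, i.e. (0, 1, 0) at 0° (viewer on the
patient's left); its sign never enters any measurement.

### 2D measurement and the closed form

On the projected image, PI is the unsigned angle between (a) the
perpendicular to the projected endplate line, erected *in the image* at the
projected endplate midpoint and taken on the hip-axis side (so the angle is
acute for realistic anatomy), and (b) the segment to the projected hip-axis
midpoint. This `in_image_perpendicular` mode is the default because it is
what a measurer drawing on a radiograph or screen capture actually does;
the projection of the fixed 3D perpendicular is *not* perpendicular in the
image once θ ≠ 0, and measuring with it (mode `projected_3d_perpendicular`,
retained for comparison) produces different off-axis values and does not
reproduce the observed trend directions.

For the idealized symmetric pelvis the whole chain collapses to

cos PI(θ) = cos θ · cos(ss + pt) / √(A·B),

with A = 1 − cos²(ss)·sin²θ, B = 1 − sin²(pt)·sin²θ for vertical rotation
and A = 1 − sin²(ss)·sin²θ, B = 1 − cos²(pt)·sin²θ for horizontal rotation.
At θ = 0 it reduces to ss + pt. The test suite holds the numeric pipeline to
this closed form within 10⁻⁶° over the grid ss ∈ {30,…,60}, pt ∈ {0,…,15},
both axes, θ ∈ {0, 5, …, 40}°; the closed form itself was derived
independently and checked against a brute-force projection of dense
idealized landmarks before being frozen into the package.

### Sweeps, the 6° criterion, cohorts, reliability

A sweep evaluates the pipeline at 0–40° in 5° steps (the published grid;
any grid containing 0° is accepted). Change is relative to the 0° value and
percentage change is computed from unrounded values — the published change
rows are consistent with unrounded, not rounded, PI rows. Rounding (PI to 1
decimal, % change to 2) happens only in the reporting layer.

The acceptability rule is made precise as: the largest tabulated angle such
that |ΔPI| ≤ tol at that angle *and every smaller one* (a prefix rule, with
an inclusive comparison so |Δ| = tol passes). The default tol of 6° is the
published variability bound for satisfactory reproducibility of repeated
angle measurements. Applied to the published vertical-rotation cohort means
the rule returns 30°, as reported. Applied to the published *horizontal*
means it returns 30° as well — |48.8 − 42.2| = 6.6° at 35° — although the
source text states 35° for horizontal rotation. The package implements the
stated criterion and documents the discrepancy rather than reproducing it;
a per-patient or unrounded-data criterion could explain the published 35°,
but no such rule is stated.

Cohort summaries are arithmetic means of per-member values at each angle,
with the threshold applied to the mean curve. ICC(3,1) — single-measure,
two-way mixed-effects, consistency form — is computed from the ANOVA mean
squares, (BMS − EMS) / (BMS + (k−1)·EMS), and classified as excellent
(≥ 0.75), fair to good (≥ 0.40) or poor (< 0.40); the published bin edges
overlap ambiguously, so boundary values are assigned to the upper bin.

## Numerical choices and degenerate inputs

* Unit-vector normalisation and angle computations guard against |cos| > 1
  roundoff; zero-length vectors below 10⁻¹² mm raise degenerate-geometry
  errors rather than returning NaN.
* Collinear circle points, < 4 or coplanar sphere points, and rank-deficient
  endplate patches raise classed degenerate-geometry errors.
* An endplate viewed end-on (projected AP direction < 10⁻⁹) raises a
  degenerate-projection error naming the angle when it occurs inside a
  sweep.
* All randomness flows through explicit integer seeds; generators save and
  restore the caller's RNG state, and cohort member seeds are derived
  deterministically from the cohort seed.

## Limitations

* Orthographic projection only: divergent (cone-beam) X-ray geometry, which
  adds a magnification-dependent error of its own, is out of scope.
* Single-axis rotations only; combined obliquity + axial rotation is not
  modeled.
* The synthetic cohort reproduces trend directions and error growth rates
  for stated parameter distributions; per-angle cohort means of any real
  patient set depend on each patient's unpublished scan-frame anatomy and
  are not exactly reproducible.
* No DICOM import, image segmentation or mesh reconstruction: the package
  starts where segmentation ends, at labeled point clouds.
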