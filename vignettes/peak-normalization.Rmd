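---
title: "Peak normalization of circumpapillary RNFLT profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak normalization of circumpapillary RNFLT profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnfltnorm)
```

## The problem

Retinal nerve fiber layer thickness (RNFLT), read along a circle of 1.7 mm
radius around the optic nerve head (ONH), is a standard OCT biomarker for
glaucoma. In healthy eyes the circumpapillary profile is double-humped,
with its thickest points — the supratemporal (ST) and infratemporal (IT)
peaks — marking the superior and inferior nerve-fiber bundles. Where those
peaks sit varies considerably between healthy individuals (roughly ±10°
SD). Because a patient's profile is judged sector by sector against a
normative band built by averaging many healthy profiles, peak-location
variability both widens that band and produces false sectoral flags when
an individual's peak is merely displaced rather than thinned.

`rnfltnorm` implements *peak normalization* (PN): each profile is warped in
angle so that its own ST and IT peaks coincide with the cohort's mean peak
locations, after which the normative band is rebuilt. The package
quantifies the effect on per-sector variability (coefficient of variation,
CoV) and on normal/borderline/abnormal categorization, and includes a
synthetic-cohort simulator so the whole pipeline is testable without any
patient data.

## Conventions

* **Grid.** Thickness maps are 200×200 rasters in µm with image x
  rightward and y downward; the default pixel pitch is 200/6 px/mm (a
  6×6 mm en-face cube). Maps are recentered by integer translation so the
  ONH sits at pixel (100, 100); exposed pixels are filled with 0. Left
  eyes are mirrored about the vertical axis through the ONH column so all
  analysis is in right-eye orientation.
* **TSNIT angle.** 0° is the 9 o'clock (temporal) position; the angle
  increases through superior (90°), nasal (180°) and inferior (270°). In
  image coordinates the unit displacement for angle θ is
  (−cos θ, −sin θ).
* **Profiles.** 720 samples at 0.5° steps, bilinear interpolation on the
  circle. Bilinear sampling is exact for affine fields, which the tests
  exploit as an oracle; nearest-neighbour sampling is kept for
  cross-checks.
* **Clock hours.** Twelve 30° sectors centred on their hour meridians,
  CH9 at 0°, CH12 at 90°, CH3 at 180°, CH6 at 270°. Sector means average
  the 60 samples of each sector. A start-at-meridian alternative is
  available via `centered = FALSE`; the centred convention is the default
  because 0° *is* CH9 in the TSNIT reading of a right eye.
* **Fovea–ONH axis (FOA).** The FOA angle is the elevation of the fovea
  relative to the ONH against the horizontal image axis, measured in a
  y-up frame, so a fovea inferior to the ONH gives a negative angle
  (healthy cohorts average about −10°). `align_foa()` applies the
  circular profile shift equivalent to rotating the image about the ONH
  until the FOA is horizontal; the tests verify this equivalence against
  a brute-force map-rotation oracle.

## Peak detection

The ST peak is the thickest sample with angle in [0°, 110°], the IT peak
the thickest in [250°, 360°], both bounds inclusive, with the 0° sample
also readable as 360° for the IT window. Detection is a plain argmax on
the 0.5° grid — no smoothing and no sub-sample refinement, because the
quantity of clinical interest is the sampled profile itself. Ties break
toward the smaller angle. A window whose samples are all equal is flagged
*degenerate*; such subjects are excluded from the cohort mean peak
locations (with a warning) but are still warped using the window argmax.

One practical observation motivates a caution: on noisy profiles the
argmax is genuinely ill-determined to a few degrees, because several
samples near the bump top compete within the noise amplitude. Peaks must
therefore be detected on exactly the profiles being warped, which is what
`analyze_cohort()` does internally.

## The warp

For targets (m_st, m_it) and individual peaks (p_st, p_it), the angular
map φ is piecewise linear through

    (0,0) → (p_st, m_st) → (180,180) → (p_it, m_it) → (360,360),

so each hemisphere is an increasing homeomorphism: the segment before the
peak is compressed exactly when the segment after it is expanded. The
output is evaluated on the regular grid by *pulling back* through φ⁻¹ and
linearly interpolating the input there — forward scattering would leave
the output off-grid. Anchors at 0° and 180° (and 360° by wraparound) are
fixed points, peak amplitudes are preserved (the output value at m equals
the input value at p), and output values can never leave the input range
because linear interpolation is a convex combination.

Two numerical choices matter:

* **Targets are snapped to the 0.5° grid** (default `snap_to_grid = TRUE`
  in `normalize_cohort()`). With an off-grid target, each warped profile
  attains its maximum at one of the two grid neighbours of m and the
  choice varies by subject, leaving a residual ±0.25° spread. Snapping
  makes φ⁻¹(m) land exactly on the detected (grid) peak, so every warped
  profile peaks at the same sample and the post-normalization
  peak-location SD is identically zero — which is also what makes
  re-normalization an exact no-op.
* **A peak sitting exactly on a hemisphere anchor** (0°, 180°, 360°)
  cannot be moved by a monotone piecewise-linear map with those anchors;
  such peaks are nudged one grid step inward before the warp is built.

Linear (rather than spline) interpolation is used throughout; the
re-warping tolerance in the tests is twice the standard linear-interp
error bound h²·max|f″|/8, estimated from discrete second differences.

## Normative limits and categorization

The normative model stores per-angle and per-clock-hour means and SDs
(n−1 denominator) and one-sided lower limits, by default the Gaussian
mean − 1.96·SD (95% level) and mean − 2.576·SD (99% level). Values at or
above the 95% limit are *normal*, between the limits *borderline*, below
the 99% limit *abnormal*; thick values are never flagged, matching
clinical RNFL practice where only thinning is pathological. Empirical
percentile limits (2.5th / 0.5th) are available via
`method = "percentile"` for cohorts where Gaussianity is doubtful; with
the simulator's Gaussian data the parametric limits hold their nominal
coverage (≈2.5% of held-out subjects below the 95% limit, verified by
simulation in the tests).

Individual categorization uses the sector-mean value against the
sector-level limits; per-angle bands are produced for plotting only.
Both the raw and the peak-normalized profile of a subject are judged
against the *un-normalized* normative model, so that any change in a
sector's label isolates the effect of moving the peaks. Subjects are
classified against the full-cohort model (no leave-one-out): with ~78
subjects the optimism from including a subject in its own reference is
small compared with the limit widths, and it mirrors how deployed
normative databases are used.

The before/after comparison pairs the twelve per-clock-hour CoV values
(CoV = 100·SD/mean) in a Wilcoxon signed-rank test. The test is
implemented in the package because the reference implementation cannot
give exact p-values in the presence of ties: zero differences are
dropped, tied absolute differences get average ranks, and for n ≤ 25 the
exact two-sided p comes from the full null distribution of the rank sum,
built by convolution over (doubled, hence integer) ranks — equivalent to
enumerating all 2ⁿ sign assignments, which is exactly how the tests
cross-check it. Larger n uses the normal approximation with tie and
continuity corrections.

## The synthetic cohort

`generate_cohort()` emulates a healthy normative cohort:

| parameter | default | rationale |
|---|---|---|
| ST peak location | N(70.5°, 10.38²), truncated to [0°, 110°] | representative healthy-cohort distribution at 1.7 mm |
| IT peak location | N(281.0°, 12.36²), truncated to [250°, 360°] | likewise |
| FOA angle | N(−10.47°, 5.44²) | fovea typically sits below the ONH |
| bump amplitude | N(100, 15²) µm, redrawn if ≤ 0 | peak ≈ 140 µm over baseline, typical of healthy bundles |
| baseline | 40 µm | temporal/nasal floor thickness |
| bump width σ | 23° | reproduces the broad TSNIT humps |
| sample noise | 4 µm i.i.d. Gaussian, floored at 0 | residual segmentation/measurement jitter |

Truncation is by redraw, not clamping, so detection stays well-posed at
the window edges. Each subject's profile is a constant baseline plus two
wrapped-Gaussian bumps plus noise; the 2D map places that profile on an
annulus spanning 1.0–2.4 mm with a 0.3 mm cosine taper, so every
supported scan radius (1.3–2.1 mm) reads back the same angular function
(the round-trip error is below 1 µm noise-free, verified in tests).
Landmarks realize the drawn FOA exactly; optional vessel masks are
one-pixel radial polylines at the peak angles plus a configurable angular
offset, which gives the vessel-location/peak-location correlation its
expected strength without modelling real vascular trees.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: multi-peak superotemporal bundles,
supra-/infra-nasal ridges, glaucomatous thinning patterns, OCT speckle
and segmentation failures, axial-length magnification, and any shape
variability not driven by the two peak locations. The practical
consequence is visible in the simulation results: because *all* flank
variability is peak-driven in the model, normalization removes a much
larger share of CoV (tens of percent in peak-flank hours) than it can in
real cohorts, where a few percent overall is typical. The *pattern* is
the transferable part: reductions concentrate around the ST/IT peak
regions and vanish in the nasal sectors, whose thickness in the model
(and largely in reality) does not depend on where the peaks sit.

## Vessel post-processing

Vessel masks are filtered to retain thick vessels (local width strictly
greater than 4 px): the mask is opened with a disc of radius
⌈width/2⌉ and surviving connected components are reconstructed whole.
The tests check the surviving set against an independent
distance-transform width oracle (width = 2·max inscribed radius).
Skeletonization is Zhang–Suen two-subiteration thinning, written in the
package since no installed R package provides topology-preserving
thinning. Mean angular vessel location at a scan radius averages the
TSNIT angles of skeleton pixels inside an annulus of ±1 px (a zero-width
circle would miss most raster pixels); for windows ending at 360°,
pixels at 0° are read as 360° so the mean is not dragged across the
seam. Arithmetic rather than circular means are used because neither
analysis window crosses the seam.

## Problem sizes and determinism

All randomness flows through explicit seeds (`cohort_config(seed = )` or
`set.seed()` before the RNG-consuming generators). The test suite uses
cohorts of 20–120 subjects for pipeline checks, 400–500 for
distribution-recovery checks, and 1,000 random warp specifications for
the warp contract; these sizes give Monte-Carlo errors comfortably
inside the asserted tolerances while keeping a full run under a minute.
The acceptance script simulates the study-sized cohort of 78 subjects
plus a 120-subject vessel cohort.

## Known limitations

* Only the two temporal peaks are normalized; profiles with prominent
  supra-/infra-nasal peaks keep their residual misalignment there.
* The warp is defined on hemispheres split at the 0°/180° axis; a peak
  detected exactly on the boundary is nudged rather than split.
* Parametric limits assume per-sector Gaussianity; use percentile limits
  for skewed cohorts (at the cost of needing larger n).
* Severely damaged profiles may have no detectable peak; degenerate
  windows are flagged rather than silently normalized, and such subjects
  should be interpreted with the raw profile in hand.
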