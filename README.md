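# rnfltnorm

Peak normalization of circumpapillary retinal nerve fiber layer
thickness (RNFLT) profiles.

## What problem this solves

RNFLT measured by OCT along a 1.7 mm circle around the optic nerve head
is a core structural biomarker for glaucoma. Healthy profiles are
double-humped, peaking at the supratemporal (ST) and infratemporal (IT)
nerve-fiber bundles — but *where* those peaks sit varies by about ±10°
between healthy individuals. That location variability widens the
normative band every patient is compared against, and a merely displaced
peak can be flagged as sectoral thinning (a false positive) or mask real
loss.

`rnfltnorm` is for OCT/glaucoma imaging researchers who want to quantify
and remove this source of normative variability. Its core operation is a
**piecewise-linear angular warp**: with hemisphere anchors fixed at 0°,
180° and 360° (TSNIT convention, 0° = 9 o'clock temporal), the map φ
takes the individual's peak locations (p_st, p_it) to the cohort mean
locations (m_st, m_it),

    φ: (0, 0), (p_st, m_st), (180, 180), (p_it, m_it), (360, 360),

linear between knots, and the warped profile is the pull-back
f ∘ φ⁻¹ evaluated on the regular 0.5° grid. Amplitudes are preserved;
only angular position changes. Around this the package provides:

* TSNIT profile extraction from ONH-centered 2D thickness maps
  (recentering, left→right-eye mirroring, bilinear circle resampling at
  1.3–2.1 mm radii), fovea–ONH-axis (FOA) rotational correction, and
  clock-hour sector statistics;
* ST/IT peak detection (thickest sample in 0–110° / 250–360°);
* normative models with Gaussian (mean − 1.96·SD / mean − 2.576·SD) or
  percentile lower limits, and normal / borderline / abnormal sector
  categorization;
* per-clock-hour coefficient-of-variation (CoV = 100·SD/mean) tables
  before and after normalization, CoV reductions, and an exact paired
  Wilcoxon signed-rank test (tie-aware, enumeration-free exact null);
* retinal-vessel mask post-processing (width filtering, Zhang–Suen
  skeletonization, polar mean-angle statistics) to correlate vessel
  locations with RNFLT peaks;
* a calibrated synthetic-cohort simulator (peak locations
  N(70.5°, 10.38²) and N(281.0°, 12.36²), FOA N(−10.47°, 5.44²)) so the
  full pipeline runs and is tested without patient data.

## Worked example

```r
library(rnfltnorm)

cohort <- generate_cohort(cohort_config(n_subjects = 78, seed = 42))
fit <- analyze_cohort(cohort, foa_align = TRUE)
fit
#> <rnflt_pn_analysis> n = 78 subjects
#>   mean peak targets: ST 71.16 deg, IT 278.81 deg
#>   mean CoV: 16.99% -> 10.01% (mean per-CH reduction 36.71%)
#>   largest reduction: CH1 (54.39%)
#>   Wilcoxon (12 paired CoVs, before vs after PN): p = 0.0004883

tidy(fit)[c(3, 6, 12), ]
#> # A tibble: 3 × 6
#>      ch cov_before cov_after_pn reduction_pn_pct cov_after_pn_foa ...
#> 1     3       1.47         1.45             1.48             1.63
#> 2     6      15.7         10.4             34.1             10.6
#> 3    12      21.4         10.7             50.1              9.92
```

Reading this: detected mean peak locations (71.2°, 278.8°) are the warp
targets; after warping every profile so its peaks sit there, the mean
per-clock-hour CoV drops from 17.0% to 10.0%, the drop concentrates in
the hours flanking the peaks (CH12 here: 50%), and the nasal sector CH3 —
whose thickness does not depend on peak position — is essentially
unchanged (1.5%). The paired Wilcoxon test across the 12 clock hours
confirms the reduction (p < 0.001). On synthetic cohorts the reductions
are much larger than in real ones, because the simulator's only shape
variability *is* peak-driven; the spatial pattern, not the magnitude, is
the point. `autoplot(fit)` draws the CoV comparison,
`autoplot(fit$normative, profile = ...)` the normative band, and
`classify_profile()` labels an individual's clock hours before and after
normalization.

Worked-example arithmetic on a published clock-hour summary table ships
with the package:

```r
ref <- reference_sector_stats()
cov_reduction(ref$cov_before_pct[ref$ch == 6], ref$cov_pn_pct[ref$ch == 6])
#> [1] 10.38
```

A thin CLI wrapping the same functions is in `inst/cli/rnfltnorm`
(subcommands `simulate`, `analyze`, `classify`).

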