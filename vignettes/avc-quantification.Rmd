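---
title: "Quantifying aortic valve calcium on contrast-enhanced CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic valve calcium on contrast-enhanced CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avcscore)
```

## The measurement problem

The calcium burden of the aortic valve predicts the severity of aortic
stenosis and is graded by the Agatston score on a native,
non-contrast-enhanced CT. In the TAVI work-up a contrast-enhanced CT
(CECT) is acquired anyway, at higher resolution, but the opacified blood
pool (several hundred HU) swallows the universal 130 HU calcium
threshold. This package implements a dynamic, patient-specific threshold
for CECT together with a linear conversion back to the familiar Agatston
scale, so that the native scan — and its radiation dose — can be omitted.

## Models and procedures

### Native Agatston scoring (the reference)

For a native volume the score is computed slab-wise on 3 mm slices:

* Thin slices (1 mm thick, reconstructed every 0.75 mm by default) are
  averaged in consecutive, non-overlapping groups into 3 mm slabs
  (`resample_slabs()`). Averaging, not maximum, approximates a genuine
  thick-slice reconstruction. A slab width that is not a whole multiple
  of the increment is an error rather than a silent rebinning; a trailing
  partial group is dropped.
* Per slab, 8-connected components of pixels with attenuation ≥ 130 HU
  form candidate lesions (`detect_lesions()`); components below 1 mm² are
  discarded. The threshold comparison is inclusive: a voxel at exactly
  130 HU counts.
* A lesion contributes area × density weight, with weights 1–4 for lesion
  maxima of 130–199, 200–299, 300–399 and ≥ 400 HU (`density_weight()`).
* The calcium *volume* is measured on the un-slabbed thin-slice grid as
  suprathreshold voxel count × `pixel² × increment`.

The 130 HU / 120 kV setting is the standard one; the bracket bounds,
minimum area and connectivity are configurable because clinical
workstations do not fully document their own choices. Adjacent calcified
structures (coronary ostia, aortic wall) are removed by an explicit
exclusion mask (`apply_exclusion()`), mirroring the manual step in
clinical scoring; excluded voxels are set to −1024 HU so no downstream
threshold can recover them.

### The dynamic CECT threshold

On the contrast-enhanced scan the calcium cutoff must sit above the
patient's own lumen enhancement. A circular ROI covering the central 2/3
of the lumen cross-section, placed 30 mm above the annulus in the
ascending aorta, gives the luminal attenuation mean μ and population SD σ
(`place_roi()`, `roi_stats()`); the segmentation threshold is

> threshold = μ + 4σ  (`dynamic_threshold()`, `k = 4` by default).

Four SDs (rather than the two or three used by some earlier approaches)
buys robustness against pixel noise at high spatial resolution. The
population SD is used because it is what scanner consoles display for an
ROI. The valve region itself is supplied as a mask (or taken as the whole
volume): automatic valve detection is out of scope, as in clinical
practice where the region is drawn semi-automatically.

`segment_calcium()` then counts voxels ≥ threshold inside the valve
region and outside exclusions; the volume convention
(`pixel² × increment`) matches the native side and the phantom ground
truth, so noise-free recovery can be exact. For overlapping
reconstructions this convention counts each 0.75 mm step once, which is
how consecutive slices tile space.

### Conversion and its calibration

Calculated Agatston units are an affine function of the CECT calcium
volume. The shipped preset `"ref-2024"` is

> calculated AU = 691 + 1.83 × AVC_CECT (mm³),

derived from a 45-subject severe-stenosis derivation cohort. The
intercept is deliberately free: such cohorts contain no low-calcium
subjects, so the best-fit line does not pass through the origin, and
forcing it to (as some earlier conversion rules did) is available only
behind `calibrate(..., zero_intercept = TRUE)` for comparison.
Conversion constants are centre- and protocol-specific; `calibrate()`
refits them by ordinary least squares from any paired cohort and reports
R² and n.

### Agreement statistics

`validate_conversion()` compares calculated against native scores with:

* **ICC**: single-measure, two-way, absolute-agreement — ICC(A,1) — the
  standard method-comparison form, computed from the ANOVA mean squares
  (rows = subjects, columns = methods) with the F-based confidence
  interval using Satterthwaite degrees of freedom. A consistency form,
  ICC(C,1), is selectable; the form used is recorded in the report. With
  zero error *and* zero method variance the interval degenerates to the
  point estimate.
* **Bland–Altman**: differences d = native − calculated (the convention
  is stated in the report) against means; bias, SD of differences, limits
  of agreement bias ± 1.96·SD, and a proportional-bias test — the
  two-sided t-test on the OLS slope of d on the means. When the
  regression is degenerate (constant d, or residuals exactly zero) the
  p-value is reported as `NA` rather than a fabricated number.
* **R²**: the squared Pearson correlation between native and calculated
  scores.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a cylindrical contrast-enhanced lumen along
the slice axis, spherical valve lesions of uniform peak HU, optional
distractor calcifications outside the valve, and i.i.d. Gaussian voxel
noise. Sphere membership is decided by voxel-centre distance, which keeps
the analytic ground truth exact: the native truth mask is the noiseless
voxels ≥ 130 HU within valve lesions, the CECT truth mask the noiseless
lesion voxels strictly above enhancement + 4 × noise SD. The true
Agatston score is computed by `reference_agatston()`, a deliberately
naive per-voxel scorer (explicit slab loops, stack-based flood fill,
inline weight brackets) that doubles as the independent check on the
production implementation.

Defaults are chosen to be realistic for a TAVI planning scan rather than
fitted to anything: 0.5 mm pixels, 1 mm slices every 0.75 mm, a 15 mm
lumen radius, 360 HU enhancement and 25 HU noise — which puts the default
dynamic threshold at 460 HU, in the range reported for clinical cohorts
(≈ 470 ± 120 HU). Scanner noise levels are not published for the clinical
protocol, so the noise default is a free parameter of the simulation.

The phantom deliberately omits partial-volume blur (an optional Gaussian
`smooth_sd_mm` adds it), beam hardening, motion, ECG-gating artifacts and
any anatomy beyond cylinder-plus-spheres. Passing phantom tests therefore
demonstrates the *computational* correctness of thresholds, connectivity,
weighting and volume conventions — not robustness to the physics of real
scans, which only clinical data can show.

`make_paired_cohort()` simulates paired native/CECT measurement tables
from a known conversion relation (defaults: n = 45, volumes uniform on
300–2500 mm³, score noise 400 AU — the scale of a severe-stenosis
derivation cohort), and `make_agreement_cohort()` simulates two-method
tables with a known population ICC (between-subject variance 1, error
variance solved from the target). These drive the statistical recovery
checks.

## Numerical choices and edge cases

* Threshold comparisons are inclusive (≥) on both the native and CECT
  side; ties at the threshold are counted.
* HU are carried as doubles throughout; NIfTI round trips are bit-exact
  (`datatype = "double"`), with a JSON sidecar for the metadata NIfTI-1
  cannot hold (slice thickness, kV, modality). A NIfTI with no usable
  spacing information is rejected, never silently defaulted.
* Axis convention is `(slice, row, col)` with physical coordinates in mm
  from the first voxel centre; all module boundaries assert geometry.
* The minimum-area rule keeps components with area ≥ 1 mm² (a 4-pixel
  component of 0.25 mm² pixels survives; 3 pixels do not).
* `calibrate()` accepts any cohort with ≥ 2 distinct volumes (the OLS
  line is determined); zero-variance volumes are an explicit error, as is
  an ICC on fewer than 5 pairs or on constant data.
* Problem sizes in the test-suite and acceptance simulations — 100 random
  phantoms for oracle equivalence, 50 noisy phantoms for recovery, 200
  calibration cohorts of n = 45, 500 agreement cohorts of n = 20 — were
  chosen so Monte-Carlo error sits well inside the asserted tolerances
  while the whole suite runs in well under a minute.

## Known limitations

* ICC(A,1) is slightly biased downward in small samples; at n = 20 the
  mean estimate under a population ICC of 0.915 is ≈ 0.905. The recovery
  checks assert the mean within ±0.02 for exactly this reason.
* The Bland–Altman proportional-bias test can flag "bias" even for a
  correct conversion, because only the native method carries noise: the
  difference is then correlated with the mean by construction. This is a
  property of the statistic, not of the implementation.
* The fixed-threshold CECT mode (300–850 HU ranges used elsewhere) is
  intentionally not implemented as a validated mode; the threshold
  argument of `segment_calcium()` makes it trivially available to users
  who want the comparison.
* No DICOM-dialect coverage; NIfTI (plus sidecar) is the interchange
  format, and conversion from DICOM is left to standard tooling.
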