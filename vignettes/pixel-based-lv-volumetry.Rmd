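---
title: "Pixel-based left-ventricular volumetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-based left-ventricular volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixelLV)
```

## The two measurement families

Short-axis cine MRI delivers a stack of slices through the left ventricle
over the cardiac cycle. The contour-surface method (disc summation) draws
the endocardial border on each slice at end-diastole (ED) and end-systole
(ES) and sums area × slice spacing. Everything inside the border counts as
blood — including the papillary muscles, which are solid tissue. The
pixel-based method instead classifies individual pixels as blood by their
intensity (blood is bright in SSFP cine, myocardium dark), so papillary
tissue inside the cavity is excluded.

If PM denotes the papillary volume enclosed by the contour, the two
families are algebraically linked:

$$ EDV_{KfM} = EDV_{PbM} + PM, \qquad ESV_{KfM} = ESV_{PbM} + PM $$

Stroke volume is therefore identical, while EF separates:

$$ EF_{PbM} = \frac{SV}{EDV_{PbM}} > \frac{SV}{EDV_{PbM} + PM} = EF_{KfM}. $$

Rearranging these identities gives four independent estimators of PM from a
pair of measurements — implemented in `estimatePM()`:
$PM_1 = EDV_{KfM} - SV_{KfM}/EF_{PbM}$,
$PM_2 = SV_{PbM}/EF_{KfM} - EDV_{PbM}$,
$PM_3 = EDV_{KfM} - EDV_{PbM}$ and
$PM_4 = ESV_{KfM} - ESV_{PbM}$.
On algebraically consistent inputs all four coincide exactly (a property the
test suite sweeps over 1000 random subjects); on real measurements their
spread reflects segmentation noise and their mean is reported. EF is held as
a fraction internally — $PM_1$ and $PM_2$ divide by it — and rendered as
percent only at I/O.

One published identity is worth flagging: the stroke-volume relation is
sometimes printed with the operands swapped (ESV − EDV), which would be
negative whenever EDV > ESV. The package uses the universal convention
SV = EDV − ESV throughout, consistent with the EF numerator.

## The brush segmentation model

The interactive tool this package reimplements lets a user "roughly colour"
the cavity with a brush; the algorithm does the precise work. Headlessly,
a `BrushStroke` is an ordered list of cursor positions with a radius and an
optional fixed intensity interval. For each position `segmentStroke()`:

1. computes minimum, maximum, mean and variance of the intensities under
   the brush disk (`computeLocalStats()`; population variance, since the
   statistic describes exactly the pixels under the brush);
2. derives an intensity interval
   $[\max(min,\ \mu - k\sigma),\ \min(max,\ \mu + k\sigma)]$
   (`deriveBounds()`). No published formula exists for this step; mean ±
   k·σ clipped to the local extrema is the simplest rule that uses all four
   statistics. `k` defaults to 2.0 (≈95% of a Gaussian blood-intensity
   population) and is user-settable. Fixed bounds, when given, override the
   derived interval entirely — this mirrors the documented clinical
   workflow, where an intensity range capturing blood is set explicitly;
3. grows the 4-connected component of in-interval pixels containing the
   seed, confined to the brush disk (`regionGrow()`). Confinement is our
   reading of "within the brush size": the full cavity emerges from the
   union over a stroke's many positions, and a stray bright structure far
   from the brush can never be captured. A seed whose own intensity falls
   outside the interval contributes an empty mask with a warning — the
   user painted non-target tissue — never an error;
4. closes the per-slice union morphologically (`applyClosing()`), filling
   pixel-scale holes that noise punches into the grown region.

All processing is strictly 2D per slice, matching the slice-wise marking
workflow. Connectivity is 4-connected; the structuring element is the set
of pixels within Euclidean distance `closingRadius` (default 1, i.e. the
plus-shaped 4-neighbourhood). The radius-1 element is deliberate: it fills
single-pixel noise holes — the closing's purpose — while a 3 × 3 box or
larger disk was observed to swallow single-pixel stair-steps of the
papillary boundary, biasing blood volumes upward; larger elements could
even bridge the cavity to the myocardium. Degenerate inputs are defined,
not exceptional: zero variance yields the single-intensity interval
[μ, μ], an empty position list yields an empty mask.

## Volumetry rules

* **Basal slice**: the most basal slice whose myocardial ring is at least
  50% closed around the blood pool (`detectBasalSlice()`). Coverage is the
  fraction of angular sectors around the blood-pool centroid containing a
  myocardium pixel within a radial band (default 20 mm) beyond the pool's
  outermost extent. The band keeps remote dark structures from counting as
  ring. We use 72 sectors (5°): a discrete pixel ring of realistic size
  occupies a few hundred pixels, which cannot populate 360 one-degree bins
  even when fully closed, whereas 5° sectors are saturated by any closed
  ring yet still resolve the 50% criterion to ±2.5°. Evidence masks
  thresholded from noisy images should be cleaned with a morphological
  opening (`cleanMask()`) first, otherwise salt noise populates sectors
  indiscriminately. If no slice qualifies the function errors: the stack
  contains no valid base.
* **Phases**: ED is the first cine image by definition; ES is the phase
  with the smallest blood-pool area on a mid-ventricular reference slice
  (`selectPhases()`, `midThirdSlice()`), ties resolving to the earliest
  phase. The clinical description of ES is subjective; the area argmin is
  the natural automation and coincides with the subjective choice whenever
  the contraction curve has a unique minimum.
* **Volume**: per-slice area (pixel count × pixel area) times inter-slice
  spacing, summed from the basal slice to the last slice with a non-empty
  mask (`phaseVolume()`, `simpsonVolume()`); empty slices below the apex
  are excluded. The spacing includes the 10% inter-slice gap by default —
  tissue in the gap still belongs to the chamber — while the protocol's
  printed voxel volume (1.8 × 2.5 × 8.0 mm = 36 mm³) is deliberately
  gap-free; `voxelVolume()` reproduces that arithmetic and
  `simpsonVolume(..., includeGap = FALSE)` makes the two views
  interconvertible.

## The digital phantom

`generatePhantom()` builds the ground-truthed test bed the real study cannot
provide (no image data were deposited). Its defaults reproduce the
acquisition geometry of a typical 1.5 T SSFP cine protocol — 192 × 109
matrix, 1.8 × 2.5 mm pixels, 8 mm slices with 10% gap, 12 slices, 25
phases — and a realistic adult LV:

* stacked concentric endo-/epicardial ellipses (basal semi-axes 34 × 28 mm,
  wall 10 mm at ED) tapering as a half-ellipsoid toward the apex; the
  stacked-ellipse shape is the simplest geometry with an analytic volume
  oracle;
* a cosine volume curve from ED (phase 1) to ES (phase 11 of 25) and back,
  scaled so the true blood pool achieves a target EF of 0.55; the wall
  thickens during systole exactly conserving the myocardial ring area, so
  myocardial mass is constant over the cycle by construction (the classic
  contour quality check) — the truth tables vary by < 0.3%, pure
  rasterization jitter;
* two papillary cylinders of radius 7 mm spanning the mid-ventricle
  (≈13 mL in-lumen total), one free in the lumen, one pressed 1.5 mm into
  the wall so its component is pixel-adjacent to myocardium — the
  luminal/wall-attached distinction commercial tools make. The bodies'
  insertion angle drifts 8° per slice: papillary muscles run obliquely,
  and the drift additionally prevents the small circles from hitting the
  pixel grid at the identical phase on every slice, which would otherwise
  accumulate coherent rasterization error;
* bright-blood contrast with blood 400, myocardium/papillary 120,
  background 40 (arbitrary units) and additive Gaussian noise of σ = 20
  (5% of blood) by default. No published intensity or noise values exist
  for the original scans; these are modelling choices producing a
  contrast-to-noise ratio at which intensity classification is easy, as it
  is in clinical SSFP. A fixed seed makes every run bit-identical.
* slice 1 is an atrial transition: a bright pool wrapped by an open 144°
  myocardial arc (40% coverage), present in the images but absent from the
  LV truth — precisely the slice the 50%-ring rule must reject.

Truth volumes are computed by sub-pixel counting on a 4× oversampled
rasterization of the analytic shapes, independent of the native grid the
segmentation sees; truth masks (blood / papillary / myocardium, pairwise
disjoint) are rasterized at pixel centres. Parts of the attached papillary
body inside the wall count as myocardium, so the papillary truth is exactly
the luminal muscle an endocardial contour would enclose.

What the phantom does *not* emulate: MRI physics (no Bloch/k-space
simulation, no partial-volume mixing, no surface-coil bias field, Gaussian
rather than Rician noise), trabeculation, papillary shape irregularity,
breathing or arrhythmia artefacts, and long-axis motion of the base.
Passing the phantom suites therefore demonstrates correctness of the
algorithms under the stated geometry and contrast model, not clinical
performance on patient data.

## Equivalence testing

`tostPaired()` implements two one-sided paired t-tests. The published
analysis specifies an equivalence margin only as "Cohen's d = 0.3"; the one
margin computable from paired data alone is d × SD of the paired
differences (the paired-d_z convention), which is what the package uses,
with d configurable. Equivalence is declared when both one-sided p-values
fall below α = 0.05. The margin is estimated from the same sample, so the
test is only asymptotically exact; at n = 50 the Monte-Carlo suite measures
a size of ≈0.04–0.05 at the margin and power ≈0.99 at zero difference with
n = 200. Differences with zero spread raise an error — the margin would be
degenerate, and two genuinely identical columns signal a data error rather
than equivalence. No multiplicity correction is applied, matching the
original analysis. `buildCohortReport()` adds the workflow's consistency
check: subjects whose stroke volumes differ by more than 15% between
methods are flagged for re-evaluation.

## Numerical and interface choices

* Arrays are `[row, col, slice, phase]`, 1-based inside R; the JSON brush
  stroke schema on disk is 0-based `(slice, row, col)` and is converted at
  the I/O boundary.
* NIfTI stores pixel spacings as float32; `readCine()` rounds them to six
  significant digits so clinical spacings like 1.8 mm are recovered
  exactly. The inter-slice gap has no NIfTI header slot and travels in a
  JSON sidecar.
* Report rounding (half-even) happens only at presentation: volumes to
  integer mL, EF to integer percent, papillary volumes to one decimal;
  every internal computation is unrounded.
* Aggregation of papillary-estimate tables uses plain arithmetic means
  along formulas, methods and overall; when several subjects share a
  method they are averaged first (means of per-subject estimates, not
  estimates of cohort means — the two differ because $PM_1$ and $PM_2$
  are nonlinear in EF).

## Problem sizes

The bundled suites run one default-geometry phantom per noise condition
(12 slices × 25 phases at 192 × 109), 1000-subject estimator sweeps, 100
random 32 × 32 oracle images for the region-growing cross-check, and
1000-replicate TOST calibrations at n = 50 and n = 200 — sizes chosen so
the full suite completes in well under a minute on a laptop while keeping
Monte-Carlo error far below the tolerances being asserted.

## Known limitations

* The brush-confinement reading ("growth limited to the brush disk") and
  the mean ± k·σ bounds rule are design decisions where the original
  description is silent; both are parameterized so alternatives can be
  explored.
* The luminal-papillary adjacency rule (per-slice 4-connectivity to
  myocardium) emulates, but cannot reproduce, the proprietary logic of
  commercial tools.
* Published per-patient tables cannot be regenerated: the underlying
  191-subject data are unavailable, and means of per-patient ratios do not
  equal ratios of cohort means. The cohort-level numbers the package does
  recompute (percent differences, table aggregation) use the published
  summary values as inputs.
* DICOM input is out of scope; NIfTI (plus the gap sidecar) is the
  interchange format.
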