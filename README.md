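# pixelLV

Pixel-based left-ventricular (LV) volumetry from short-axis cine MRI.

## The problem

LV function parameters — end-diastolic volume (EDV), end-systolic volume
(ESV), stroke volume (SV = EDV − ESV) and ejection fraction
(EF = SV / EDV) — steer therapy decisions such as valve replacement and ICD
implantation. The conventional contour-surface (disc-summation) method draws
the endocardial border on every short-axis slice, so by construction the
papillary muscles inside that border are counted as blood. This inflates EDV
and ESV by the papillary-muscle volume PM, leaves SV untouched
(the same PM is added at both phases) and biases EF downward:

    EF_contour = SV / (EDV_pixel + PM)  <  EF_pixel = SV / EDV_pixel

`pixelLV` implements the pixel-based alternative: classify voxels as blood by
intensity (bright-blood SSFP contrast) so the papillary muscle is naturally
excluded, and quantify the difference between the two method families. It is
aimed at cardiac-MRI methodologists who want a scriptable, fully testable
implementation of the pixel-based workflow, including a ground-truthed
digital phantom so every stage can be validated without patient data.

## What is inside

* **Phantom** (`generatePhantom`, `phantomParams`, `imageGeometry`) — a
  synthetic contracting LV as a 4D cine stack (default: 192 × 109 matrix,
  1.8 × 2.5 mm pixels, 8 mm slices + 10% gap, 12 slices, 25 phases) with
  exact per-phase truth volumes and masks for blood, papillary muscle and
  myocardium.
* **Segmentation** (`segmentStroke`, `computeLocalStats`, `deriveBounds`,
  `regionGrow`, `applyClosing`, `cleanMask`) — the headless brush: local
  intensity statistics under the brush disk, mean ± k·σ threshold bounds
  (or fixed bounds), seed-constrained 4-connected region growing confined to
  the brush, and a per-slice morphological closing.
* **Volumetry** (`detectBasalSlice`, `selectPhases`, `maskArea`,
  `simpsonVolume`, `phaseVolume`, `computeFunctionParams`) — the 50%
  myocardial-ring basal-slice rule, first-image ED / smallest-mid-cavity ES
  selection, and Simpson (summation-of-discs) volumes.
* **Contour reference** (`endocardialFill`, `luminalPapillaryVolume`) — a
  mask-level emulation of the contour-surface method and of the
  luminal-only papillary segmentation of commercial tools.
* **Papillary estimators** (`estimatePM`, `aggregatePmTable`) — the four
  closed-form PM estimators
  PM1 = EDV_KfM − SV_KfM / EF_PbM, PM2 = SV_PbM / EF_KfM − EDV_PbM,
  PM3 = EDV_KfM − EDV_PbM, PM4 = ESV_KfM − ESV_PbM, and their aggregation
  into a formula × method table.
* **Statistics** (`tostPaired`, `percentDifference`, `buildCohortReport`) —
  paired TOST equivalence testing with a Cohen's d margin (default d = 0.3,
  margin = d × SD of the paired differences), cohort summaries, and the
  15% stroke-volume consistency check.
* **I/O** (`readCine`, `writeCine`, `writeMask`, `readBrushStroke`, ...) —
  4D NIfTI stacks and masks, JSON brush strokes (0-based on disk), JSON/CSV
  parameter and report files. A thin CLI (`inst/scripts/pixellv`) exposes
  `simulate`, `segment`, `volumetry`, `compare` and `report` subcommands.

## Worked example

Generate a noisy phantom, run the pixel-based pipeline against the emulated
contour reference, and estimate the papillary-muscle volume:

```r
library(pixelLV)

ph  <- generatePhantom(phantomParams(), imageGeometry(), seed = 1)
ph$truth
#> PhantomTruth: 25 phases; ED phase 1 (blood 180.1 mL), ES phase 11
#>   (blood 81.1 mL), papillary 13.0 mL, basal slice 2

g   <- geometry(ph$stack)
tr  <- ph$truth
img <- intensities(ph$stack)

# basal slice (50%-ring rule) and ED/ES phases from the images
basal  <- detectBasalSlice(cleanMask(img[,,,1] >= 60 & img[,,,1] <= 180),
                           cleanMask(img[,,,1] >= 260), g)
phases <- unname(selectPhases(ph$stack, midThirdSlice(basal, g@nSlices),
                              threshold = 260))

# pixel-based volumes from scripted brush strokes over the blood pool
pbmVol <- function(p) {
  stroke <- strokeFromMask(tr@bloodMask[,,,p], radius = 4, step = 2,
                           phase = p, fixedBounds = c(260, Inf))
  phaseVolume(segmentStroke(ph$stack, stroke), g, basal)
}
# contour-surface volumes: endocardial fill encloses the papillary muscle
kfmVol <- function(p) phaseVolume(endocardialFill(tr@bloodMask[,,,p],
                                    tr@papillaryMask[,,,p]), g, basal)

pbm <- computeFunctionParams(pbmVol(phases[1]), pbmVol(phases[2]), "PbM")
kfm <- computeFunctionParams(kfmVol(phases[1]), kfmVol(phases[2]), "KfM")
pbm
#> FunctionParams [PbM]: EDV 180.7 mL, ESV 81.0 mL, SV 99.7 mL, EF 55.2%
kfm
#> FunctionParams [KfM]: EDV 193.4 mL, ESV 93.9 mL, SV 99.6 mL, EF 51.5%

estimatePM(kfm, pbm)
#> PMEstimates: PM1 13.0, PM2 13.0, PM3 12.8, PM4 12.9, mean 12.9 mL
```

The pixel-based EDV/ESV land within a fraction of a percent of the phantom
truth (180.1 / 81.1 mL), the two stroke volumes agree to 0.1 mL while the
EFs differ by 3.7 percentage points, and all four estimators recover the
13.0 mL of papillary muscle actually embedded in the phantom to within the
rasterization error of the pixel grid.

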