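#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition geometry of a short-axis cine stack
#'
#' Voxel spacings, slice thickness, inter-slice gap and stack dimensions of a
#' short-axis SSFP cine acquisition. The gap is stored as a fraction of the
#' slice thickness (a typical clinical protocol uses 10%), so the
#' centre-to-centre slice spacing is \code{sliceThickness * (1 + gapFraction)}.
#'
#' @slot spacingRow in-plane pixel spacing along rows, mm.
#' @slot spacingCol in-plane pixel spacing along columns, mm.
#' @slot sliceThickness slice thickness, mm.
#' @slot gapFraction inter-slice gap as a fraction of the slice thickness
#'   (dimensionless, >= 0).
#' @slot nSlices number of short-axis slices (>= 3).
#' @slot nPhases number of cine phases (>= 2).
#'
#' @seealso [imageGeometry()], [voxelVolume()]
#' @exportClass ImageGeometry
setClass("ImageGeometry",
  representation(
    spacingRow = "numeric",
    spacingCol = "numeric",
    sliceThickness = "numeric",
    gapFraction = "numeric",
    nSlices = "integer",
    nPhases = "integer"
  )
)

setValidity("ImageGeometry", function(object) {
  msg <- character()
  for (s in c("spacingRow", "spacingCol", "sliceThickness")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(object@gapFraction) != 1L || !is.finite(object@gapFraction) ||
      object@gapFraction < 0)
    msg <- c(msg, "'gapFraction' must be a single non-negative number")
  if (length(object@nSlices) != 1L || is.na(object@nSlices) ||
      object@nSlices < 3L)
    msg <- c(msg, "'nSlices' must be >= 3")
  if (length(object@nPhases) != 1L || is.na(object@nPhases) ||
      object@nPhases < 2L)
    msg <- c(msg, "'nPhases' must be >= 2")
  if (length(msg)) msg else TRUE
})

#' A 4D short-axis cine stack
#'
#' Holds the image intensities of a short-axis cine acquisition as a 4D array
#' indexed \code{[row, col, slice, phase]} together with its
#' \linkS4class{ImageGeometry}. Intensities are in arbitrary units and must be
#' finite and non-negative.
#'
#' @slot intensities 4D numeric array \code{[row, col, slice, phase]}.
#' @slot geometry an \linkS4class{ImageGeometry}.
#'
#' @seealso [cineStack()], [readCine()], [generatePhantom()]
#' @exportClass CineStack
setClass("CineStack",
  representation(
    intensities = "array",
    geometry = "ImageGeometry"
  )
)

setValidity("CineStack", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 4L) {
    msg <- c(msg, "'intensities' must be a 4D array [row, col, slice, phase]")
  } else {
    g <- object@geometry
    if (d[3L] != g@nSlices)
      msg <- c(msg, "slice dimension does not match geometry nSlices")
    if (d[4L] != g@nPhases)
      msg <- c(msg, "phase dimension does not match geometry nPhases")
  }
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A scripted brush stroke
#'
#' A headless stand-in for the interactive brush of the pixel-based method: an
#' ordered list of cursor positions, the brush radius in pixels, the cine phase
#' the stroke annotates, and optional fixed intensity bounds that override the
#' locally derived ones.
#'
#' Positions are stored 1-based as a matrix with columns (slice, row, col); the
#' JSON serialization ([writeBrushStroke()]) uses 0-based indices.
#'
#' @slot positions integer matrix, one row per cursor position, columns
#'   (slice, row, col), 1-based.
#' @slot radius brush radius in pixels (>= 1).
#' @slot phase 1-based cine phase index the stroke belongs to.
#' @slot fixedBounds optional numeric (lo, hi) intensity pair, or NULL.
#'
#' @seealso [brushStroke()], [segmentStroke()], [strokeFromMask()]
#' @exportClass BrushStroke
setClass("BrushStroke",
  representation(
    positions = "matrix",
    radius = "numeric",
    phase = "integer",
    fixedBounds = "numericOrNULL"
  )
)

setValidity("BrushStroke", function(object) {
  msg <- character()
  p <- object@positions
  if (ncol(p) != 3L)
    msg <- c(msg, "'positions' must have 3 columns (slice, row, col)")
  if (nrow(p) > 0L && (anyNA(p) || any(p < 1L)))
    msg <- c(msg, "positions must be 1-based positive indices")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius < 1)
    msg <- c(msg, "'radius' must be >= 1 pixel")
  if (length(object@phase) != 1L || is.na(object@phase) || object@phase < 1L)
    msg <- c(msg, "'phase' must be a positive 1-based index")
  if (!is.null(object@fixedBounds)) {
    fb <- object@fixedBounds
    if (length(fb) != 2L || anyNA(fb) || fb[1L] > fb[2L])
      msg <- c(msg, "'fixedBounds' must be (lo, hi) with lo <= hi")
  }
  if (length(msg)) msg else TRUE
})

#' Local intensity statistics under the brush
#'
#' Minimum, maximum, mean and variance of the intensities in a circular brush
#' neighbourhood, used to derive the region-growing intensity bounds.
#' The variance uses the population convention (denominator N), appropriate
#' for describing the pixel population actually under the brush.
#'
#' @slot minimum,maximum,mean,variance summary statistics, arbitrary
#'   intensity units.
#' @slot n number of in-bounds pixels the statistics were computed over.
#'
#' @seealso [computeLocalStats()], [deriveBounds()]
#' @exportClass LocalStats
setClass("LocalStats",
  representation(
    minimum = "numeric",
    maximum = "numeric",
    mean = "numeric",
    variance = "numeric",
    n = "integer"
  )
)

setValidity("LocalStats", function(object) {
  msg <- character()
  if (object@variance < 0) msg <- c(msg, "'variance' must be >= 0")
  if (!(object@minimum <= object@mean && object@mean <= object@maximum))
    msg <- c(msg, "must satisfy minimum <= mean <= maximum")
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Left-ventricular function parameters for one subject and method
#'
#' End-diastolic volume (EDV), end-systolic volume (ESV), stroke volume
#' (SV = EDV - ESV) and ejection fraction (EF = SV/EDV, stored as a fraction)
#' with a label naming the measurement method.
#'
#' @slot edv,esv,sv volumes in mL.
#' @slot ef ejection fraction as a fraction in [0, 1] (rendered as % at I/O).
#' @slot method method label, e.g. "PbM" or "KfM".
#'
#' @seealso [computeFunctionParams()]
#' @exportClass FunctionParams
setClass("FunctionParams",
  representation(
    edv = "numeric",
    esv = "numeric",
    sv = "numeric",
    ef = "numeric",
    method = "character"
  )
)

setValidity("FunctionParams", function(object) {
  msg <- character()
  if (object@esv < 0 || object@edv < object@esv)
    msg <- c(msg, "must satisfy EDV >= ESV >= 0")
  if (abs(object@sv - (object@edv - object@esv)) > 1e-9 * max(1, object@edv))
    msg <- c(msg, "SV must equal EDV - ESV")
  if (object@edv > 0 &&
      abs(object@ef - object@sv / object@edv) > 1e-12)
    msg <- c(msg, "EF must equal SV / EDV")
  if (length(msg)) msg else TRUE
})

#' Papillary-muscle volume estimates
#'
#' The four closed-form papillary-muscle volume estimators obtained by
#' comparing contour-surface (KfM) and pixel-based (PbM) function parameters,
#' plus their arithmetic mean. On algebraically consistent inputs
#' (KfM = PbM + PM) all four coincide.
#'
#' @slot pm1 EDV_KfM - SV_KfM / EF_PbM, mL.
#' @slot pm2 SV_PbM / EF_KfM - EDV_PbM, mL.
#' @slot pm3 EDV_KfM - EDV_PbM, mL.
#' @slot pm4 ESV_KfM - ESV_PbM, mL.
#' @slot meanPM arithmetic mean of the four, mL.
#'
#' @seealso [estimatePM()], [aggregatePmTable()]
#' @exportClass PMEstimates
setClass("PMEstimates",
  representation(
    pm1 = "numeric", pm2 = "numeric", pm3 = "numeric", pm4 = "numeric",
    meanPM = "numeric"
  )
)

setValidity("PMEstimates", function(object) {
  m <- mean(c(object@pm1, object@pm2, object@pm3, object@pm4))
  if (abs(object@meanPM - m) > 1e-9 * max(1, abs(m)))
    "meanPM must be the arithmetic mean of pm1..pm4" else TRUE
})

#' Result of a paired TOST equivalence test
#'
#' Two one-sided paired t-tests against an equivalence margin expressed as a
#' Cohen's d multiple of the standard deviation of the paired differences.
#' Equivalence is declared when both one-sided p-values fall below alpha.
#'
#' @slot meanDiff mean paired difference (a - b).
#' @slot sdDiff sample SD of the paired differences.
#' @slot margin equivalence margin, same units as the data.
#' @slot pLower p-value of the test against the lower bound (-margin).
#' @slot pUpper p-value of the test against the upper bound (+margin).
#' @slot equivalent logical verdict.
#' @slot alpha significance level.
#' @slot cohensD observed paired Cohen's d (meanDiff / sdDiff).
#' @slot n number of pairs.
#'
#' @seealso [tostPaired()]
#' @exportClass TOSTResult
setClass("TOSTResult",
  representation(
    meanDiff = "numeric", sdDiff = "numeric", margin = "numeric",
    pLower = "numeric", pUpper = "numeric", equivalent = "logical",
    alpha = "numeric", cohensD = "numeric", n = "integer"
  )
)

setValidity("TOSTResult", function(object) {
  msg <- character()
  if (object@pLower < 0 || object@pLower > 1 ||
      object@pUpper < 0 || object@pUpper > 1)
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (!identical(object@equivalent,
                 object@pLower < object@alpha && object@pUpper < object@alpha))
    msg <- c(msg, "'equivalent' must be (pLower < alpha) && (pUpper < alpha)")
  if (length(msg)) msg else TRUE
})

#' Ground truth accompanying a synthetic cine phantom
#'
#' Per-phase true volumes and per-voxel truth masks of a generated phantom:
#' blood pool, papillary muscle (split into luminal and wall-attached
#' components) and myocardium, plus the true basal slice and ED/ES phases.
#' Volumes come from voxel counting on an oversampled rasterization of the
#' analytic shapes, so they are independent of the native pixel grid.
#'
#' @slot volumes data.frame with one row per phase: \code{phase} (1-based),
#'   \code{blood_mL}, \code{papillary_mL}, \code{papillary_luminal_mL},
#'   \code{papillary_wall_mL}, \code{myocardium_mL}.
#' @slot bloodMask,papillaryMask,myocardiumMask 4D logical arrays
#'   \code{[row, col, slice, phase]}, pairwise disjoint.
#' @slot basalSlice 1-based index of the true basal slice.
#' @slot edPhase,esPhase 1-based indices of end-diastole and end-systole.
#'
#' @seealso [generatePhantom()]
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    volumes = "data.frame",
    bloodMask = "array",
    papillaryMask = "array",
    myocardiumMask = "array",
    basalSlice = "integer",
    edPhase = "integer",
    esPhase = "integer"
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  need <- c("phase", "blood_mL", "papillary_mL", "papillary_luminal_mL",
            "papillary_wall_mL", "myocardium_mL")
  if (!all(need %in% names(object@volumes)))
    msg <- c(msg, "volumes data.frame is missing required columns")
  else {
    v <- object@volumes
    if (any(v$blood_mL < 0) || any(v$papillary_mL < 0) ||
        any(v$myocardium_mL < 0))
      msg <- c(msg, "volumes must be non-negative")
    if (any(abs(v$papillary_mL -
                (v$papillary_luminal_mL + v$papillary_wall_mL)) >
            1e-6 * pmax(1, v$papillary_mL)))
      msg <- c(msg, "papillary total must equal luminal + wall-attached")
  }
  if (any(object@bloodMask & object@papillaryMask) ||
      any(object@bloodMask & object@myocardiumMask) ||
      any(object@papillaryMask & object@myocardiumMask))
    msg <- c(msg, "truth masks must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic cine phantom
#'
#' Analytic description of the digital left-ventricle phantom: a stack of
#' concentric endo-/epicardial ellipses tapering toward the apex, contracting
#' along a cosine volume curve between end-diastole (phase 1) and a
#' configurable end-systolic phase, with cylindrical papillary bodies of known
#' volume in the lumen and bright-blood / dark-myocardium SSFP-like contrast.
#'
#' @slot nRow,nCol image matrix size.
#' @slot radiusRow,radiusCol end-diastolic endocardial semi-axes at the base,
#'   mm (row/col directions).
#' @slot wallThickness end-diastolic myocardial wall thickness, mm; during
#'   contraction the wall thickens so that the myocardial ring area (hence
#'   mass) is conserved.
#' @slot ef target ejection fraction of the true blood pool (fraction).
#' @slot esPhase 1-based end-systolic phase index.
#' @slot papillary data.frame describing the papillary bodies: \code{angle}
#'   (degrees), \code{radialFrac} (centre position as a fraction of the local
#'   endocardial radius; ignored for attached bodies), \code{radius} (mm),
#'   \code{attached} (logical: pressed into the wall or free in the lumen).
#'   Zero rows means no papillary muscle.
#' @slot papillarySpan two fractions of the included stack depth between which
#'   the papillary bodies extend.
#' @slot papillaryTwist angular drift of the papillary bodies per slice,
#'   degrees (papillary muscles run obliquely, not as straight vertical
#'   columns).
#' @slot bloodIntensity,myoIntensity,backgroundIntensity mean intensities,
#'   arbitrary units; blood must exceed myocardium (bright-blood contrast).
#' @slot noiseSd standard deviation of additive Gaussian noise, intensity
#'   units.
#' @slot basalArcDeg angular extent (degrees) of the open myocardial arc on
#'   the atrial transition slice above the base (drawn in the image, excluded
#'   from the LV truth).
#' @slot oversample linear oversampling factor for truth-volume rasterization
#'   (>= 4).
#'
#' @seealso [phantomParams()], [generatePhantom()]
#' @exportClass PhantomParams
setClass("PhantomParams",
  representation(
    nRow = "integer", nCol = "integer",
    radiusRow = "numeric", radiusCol = "numeric",
    wallThickness = "numeric",
    ef = "numeric", esPhase = "integer",
    papillary = "data.frame",
    papillarySpan = "numeric",
    papillaryTwist = "numeric",
    bloodIntensity = "numeric", myoIntensity = "numeric",
    backgroundIntensity = "numeric",
    noiseSd = "numeric",
    basalArcDeg = "numeric",
    oversample = "integer"
  )
)

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (object@bloodIntensity <= object@myoIntensity)
    msg <- c(msg, "blood intensity must exceed myocardium intensity")
  if (object@ef <= 0 || object@ef >= 1)
    msg <- c(msg, "'ef' must lie strictly between 0 and 1")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@wallThickness <= 0) msg <- c(msg, "'wallThickness' must be > 0")
  if (length(object@papillarySpan) != 2L ||
      object@papillarySpan[1L] >= object@papillarySpan[2L] ||
      object@papillarySpan[1L] < 0 || object@papillarySpan[2L] > 1)
    msg <- c(msg, "'papillarySpan' must be increasing fractions in [0, 1]")
  if (nrow(object@papillary) > 0L) {
    need <- c("angle", "radialFrac", "radius", "attached")
    if (!all(need %in% names(object@papillary)))
      msg <- c(msg, "papillary table needs columns angle, radialFrac, radius, attached")
    else if (any(object@papillary$radius <= 0))
      msg <- c(msg, "papillary radii must be > 0")
  }
  if (object@oversample < 4L)
    msg <- c(msg, "'oversample' must be >= 4")
  if (length(msg)) msg else TRUE
})
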