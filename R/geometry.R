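#' Construct an ImageGeometry
#'
#' Defaults reproduce a typical clinical short-axis SSFP cine protocol:
#' 1.8 x 2.5 mm in-plane voxels, 8 mm slices with a 10% gap, 12 slices and
#' 25 reconstructed cardiac phases.
#'
#' @param spacingRow,spacingCol in-plane pixel spacings, mm.
#' @param sliceThickness slice thickness, mm.
#' @param gapFraction inter-slice gap as a fraction of the slice thickness.
#' @param nSlices,nPhases stack dimensions.
#' @return An \linkS4class{ImageGeometry}.
#' @examples
#' g <- imageGeometry()
#' voxelVolume(g)  # 36 mm^3
#' @export
imageGeometry <- function(spacingRow = 1.8, spacingCol = 2.5,
                          sliceThickness = 8, gapFraction = 0.1,
                          nSlices = 12L, nPhases = 25L) {
  new("ImageGeometry",
      spacingRow = as.numeric(spacingRow),
      spacingCol = as.numeric(spacingCol),
      sliceThickness = as.numeric(sliceThickness),
      gapFraction = as.numeric(gapFraction),
      nSlices = as.integer(nSlices),
      nPhases = as.integer(nPhases))
}

#' Volume of a single voxel
#'
#' The product of the in-plane spacings and the slice thickness. The
#' inter-slice gap is deliberately not included here: it belongs to the slice
#' spacing used in Simpson summation (see [simpsonVolume()]), not to the
#' voxel itself.
#'
#' @param geometry an \linkS4class{ImageGeometry}.
#' @return Voxel volume in mm^3.
#' @examples
#' voxelVolume(imageGeometry(1.8, 2.5, 8))  # 36
#' @export
voxelVolume <- function(geometry) {
  stopifnot(is(geometry, "ImageGeometry"))
  geometry@spacingRow * geometry@spacingCol * geometry@sliceThickness
}

#' Centre-to-centre slice spacing
#'
#' @param geometry an \linkS4class{ImageGeometry}.
#' @param includeGap include the inter-slice gap (default TRUE).
#' @return Spacing in mm.
#' @export
sliceSpacing <- function(geometry, includeGap = TRUE) {
  stopifnot(is(geometry, "ImageGeometry"))
  geometry@sliceThickness * (1 + if (includeGap) geometry@gapFraction else 0)
}

#' Construct a CineStack
#'
#' @param intensities 4D numeric array \code{[row, col, slice, phase]}.
#' @param geometry an \linkS4class{ImageGeometry} matching the array.
#' @return A \linkS4class{CineStack}.
#' @export
cineStack <- function(intensities, geometry) {
  new("CineStack", intensities = intensities, geometry = geometry)
}

#' @describeIn cineStack Access the geometry of a CineStack.
#' @param x a \linkS4class{CineStack}.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname cineStack
#' @export
setMethod("geometry", "CineStack", function(x) x@geometry)

#' @describeIn cineStack Access the intensity array of a CineStack.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname cineStack
#' @export
setMethod("intensities", "CineStack", function(x) x@intensities)

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf(
    "ImageGeometry: %.2f x %.2f mm in-plane, %.1f mm slices (+%.0f%% gap), %d slices x %d phases\n",
    object@spacingRow, object@spacingCol, object@sliceThickness,
    100 * object@gapFraction, object@nSlices, object@nPhases))
})

setMethod("show", "CineStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("CineStack: %d x %d pixels, %d slices, %d phases\n",
              d[1L], d[2L], d[3L], d[4L]))
  show(object@geometry)
})

setMethod("show", "FunctionParams", function(object) {
  cat(sprintf("FunctionParams [%s]: EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%\n",
              object@method, object@edv, object@esv, object@sv,
              100 * object@ef))
})

setMethod("show", "TOSTResult", function(object) {
  cat(sprintf(
    "Paired TOST (n = %d): mean diff %.3f, margin +/-%.3f, p_lower %.3g, p_upper %.3g -> %s\n",
    object@n, object@meanDiff, object@margin, object@pLower, object@pUpper,
    if (object@equivalent) "equivalent" else "not equivalent"))
})

setMethod("show", "PMEstimates", function(object) {
  cat(sprintf("PMEstimates: PM1 %.1f, PM2 %.1f, PM3 %.1f, PM4 %.1f, mean %.1f mL\n",
              object@pm1, object@pm2, object@pm3, object@pm4, object@meanPM))
})

setMethod("show", "PhantomTruth", function(object) {
  v <- object@volumes
  cat(sprintf(
    "PhantomTruth: %d phases; ED phase %d (blood %.1f mL), ES phase %d (blood %.1f mL), papillary %.1f mL, basal slice %d\n",
    nrow(v), object@edPhase, v$blood_mL[object@edPhase], object@esPhase,
    v$blood_mL[object@esPhase], v$papillary_mL[object@edPhase],
    object@basalSlice))
})
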