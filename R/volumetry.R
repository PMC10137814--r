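#' Area of a binary slice mask
#'
#' @param mask logical/binary 2D matrix.
#' @param geometry an \linkS4class{ImageGeometry}.
#' @return Area in mm^2 (pixel count times in-plane pixel area).
#' @examples
#' mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
#' maskArea(mask, imageGeometry())  # 100 * 1.8 * 2.5 = 450
#' @export
maskArea <- function(mask, geometry) {
  stopifnot(is(geometry, "ImageGeometry"))
  sum(mask != 0) * geometry@spacingRow * geometry@spacingCol
}

#' Simpson-rule (summation-of-discs) volume from per-slice areas
#'
#' Each slice contributes its blood-pool area times the inter-slice spacing;
#' the sum is the chamber volume. By default the spacing includes the
#' inter-slice gap (tissue in the gap still belongs to the chamber); with
#' \code{includeGap = FALSE} only the slice thickness is used, matching plain
#' voxel-count arithmetic.
#'
#' @param areas numeric vector of per-slice areas, mm^2.
#' @param geometry an \linkS4class{ImageGeometry}.
#' @param includeGap include the gap in the slice spacing (default TRUE).
#' @return Volume in mL.
#' @examples
#' simpsonVolume(rep(1500, 10), imageGeometry())  # 10*1500*8.8/1000 = 132
#' @export
simpsonVolume <- function(areas, geometry, includeGap = TRUE) {
  stopifnot(is(geometry, "ImageGeometry"))
  if (length(areas) == 0L) return(0)
  if (any(areas < 0)) stop("slice areas must be non-negative")
  sum(areas) * sliceSpacing(geometry, includeGap) / 1000
}

#' Detect the basal slice by the 50% myocardial-ring rule
#'
#' Scans from the first slice toward the apex and returns the most basal
#' slice whose myocardial ring is at least half closed around the blood pool.
#' Coverage is measured by binning the myocardium pixels that lie outside the
#' blood pool (but within a radial band beyond its outermost extent) into
#' angular sectors around the blood-pool centroid and counting the fraction
#' of occupied sectors.
#'
#' @param myocardium logical 3D array \code{[row, col, slice]} of myocardium
#'   evidence (e.g. a segmented or truth ring mask), or a 2D matrix for a
#'   single slice.
#' @param blood matching blood-pool mask (3D array or 2D matrix).
#' @param geometry an \linkS4class{ImageGeometry} (for the mm radial band).
#' @param minCoverage required closed fraction of the ring (default 0.5).
#' @param nBins number of angular bins (default 72, i.e. 5-degree sectors —
#'   coarse enough that a closed discrete pixel ring occupies every bin).
#' @param bandMm radial band beyond the outermost blood-pool radius within
#'   which myocardium pixels count, mm.
#' @return 1-based index of the basal slice. Errors when no slice qualifies.
#' @export
detectBasalSlice <- function(myocardium, blood, geometry = imageGeometry(),
                             minCoverage = 0.5, nBins = 72L, bandMm = 20) {
  if (is.matrix(myocardium)) myocardium <- array(myocardium, c(dim(myocardium), 1L))
  if (is.matrix(blood)) blood <- array(blood, c(dim(blood), 1L))
  stopifnot(identical(dim(myocardium), dim(blood)))
  for (sl in seq_len(dim(blood)[3L])) {
    bl <- blood[, , sl] != 0
    if (!any(bl)) next
    if (ringCoverage(myocardium[, , sl] != 0, bl, geometry,
                     nBins = nBins, bandMm = bandMm) >= minCoverage)
      return(sl)
  }
  stop("no slice has a myocardial ring at least ",
       round(100 * minCoverage), "% closed: the stack does not contain a ",
       "valid cardiac base")
}

#' Angular closure of the myocardial ring around the blood pool
#'
#' @inheritParams detectBasalSlice
#' @param myocardium,blood logical 2D matrices for one slice.
#' @return Fraction in [0, 1] of angular bins containing myocardium.
#' @export
ringCoverage <- function(myocardium, blood, geometry = imageGeometry(),
                         nBins = 72L, bandMm = 20) {
  stopifnot(any(blood))
  bIdx <- which(blood, arr.ind = TRUE)
  bx <- bIdx[, 1L] * geometry@spacingRow
  by <- bIdx[, 2L] * geometry@spacingCol
  cx <- mean(bx); cy <- mean(by)
  rBlood <- sqrt((bx - cx)^2 + (by - cy)^2)
  if (!any(myocardium)) return(0)
  mIdx <- which(myocardium, arr.ind = TRUE)
  mx <- mIdx[, 1L] * geometry@spacingRow - cx
  my <- mIdx[, 2L] * geometry@spacingCol - cy
  r <- sqrt(mx^2 + my^2)
  keep <- r > 0 & r <= max(rBlood) + bandMm
  if (!any(keep)) return(0)
  theta <- atan2(my[keep], mx[keep])
  bins <- pmin(nBins, floor((theta + pi) / (2 * pi) * nBins) + 1L)
  length(unique(bins)) / nBins
}

#' Select end-diastolic and end-systolic phases
#'
#' End-diastole is the first image of the cine sequence; end-systole is the
#' phase with the smallest blood-pool area on a mid-ventricular reference
#' slice (ties break to the lowest phase index).
#'
#' @param masks logical 4D array \code{[row, col, slice, phase]} of blood
#'   masks, or a \linkS4class{CineStack} together with a `threshold` above
#'   which a pixel counts as blood.
#' @param midSlice 1-based reference slice in the middle third of the
#'   ventricle.
#' @param threshold intensity threshold when `masks` is a CineStack.
#' @return Integer vector \code{c(ed, es)} of 1-based phase indices.
#' @export
selectPhases <- function(masks, midSlice, threshold = NULL) {
  if (is(masks, "CineStack")) {
    if (is.null(threshold))
      stop("a 'threshold' is required to select phases from intensities")
    masks <- intensities(masks) >= threshold
  }
  stopifnot(length(dim(masks)) == 4L)
  nP <- dim(masks)[4L]
  if (nP < 2L) stop("phase selection needs at least 2 phases")
  areas <- vapply(seq_len(nP), function(t) sum(masks[, , midSlice, t] != 0),
                  numeric(1))
  if (all(areas == 0))
    stop("the reference slice has an empty blood mask in every phase")
  c(ed = 1L, es = which.min(areas))
}

#' Compute LV function parameters from end-diastolic and end-systolic volumes
#'
#' Stroke volume is EDV - ESV and ejection fraction SV / EDV (stored as a
#' fraction; multiply by 100 for percent).
#'
#' @param edv,esv volumes in mL; requires \code{edv >= esv >= 0, edv > 0}.
#' @param method method label carried through reports.
#' @return A \linkS4class{FunctionParams}.
#' @examples
#' computeFunctionParams(100, 50)  # SV 50 mL, EF 50%
#' @export
computeFunctionParams <- function(edv, esv, method = "PbM") {
  if (edv <= 0) stop("EDV must be positive")
  if (esv < 0) stop("ESV must be non-negative")
  if (esv > edv)
    stop("ESV exceeds EDV: the ED/ES phases are probably mislabelled")
  sv <- edv - esv
  new("FunctionParams", edv = edv, esv = esv, sv = sv, ef = sv / edv,
      method = method)
}

#' Chamber volume of one phase of a segmented stack
#'
#' Sums per-slice mask areas from the basal slice down to the last slice with
#' a non-empty mask (apical termination: empty slices below the last
#' non-empty one are excluded) and applies the Simpson summation.
#'
#' @param mask3d logical 3D array \code{[row, col, slice]} for one phase.
#' @param geometry an \linkS4class{ImageGeometry}.
#' @param basalSlice 1-based first included slice.
#' @param includeGap passed to [simpsonVolume()].
#' @return Volume in mL.
#' @export
phaseVolume <- function(mask3d, geometry, basalSlice = 1L,
                        includeGap = TRUE) {
  stopifnot(length(dim(mask3d)) == 3L)
  nS <- dim(mask3d)[3L]
  areas <- vapply(seq_len(nS), function(sl) maskArea(mask3d[, , sl], geometry),
                  numeric(1))
  if (basalSlice > 1L) areas[seq_len(basalSlice - 1L)] <- 0
  nonEmpty <- which(areas > 0)
  if (length(nonEmpty) == 0L) return(0)
  simpsonVolume(areas[basalSlice:max(nonEmpty)], geometry, includeGap)
}

#' Mid-ventricular reference slice for ES selection
#'
#' The slice in the middle third of the included stack: basal slice plus half
#' the number of included slices.
#'
#' @param basalSlice 1-based basal slice index.
#' @param nSlices total slices in the stack.
#' @return 1-based slice index.
#' @export
midThirdSlice <- function(basalSlice, nSlices) {
  basalSlice + (nSlices - basalSlice + 1L) %/% 2L
}
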