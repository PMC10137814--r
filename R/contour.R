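#' Emulated endocardial contour fill
#'
#' The contour-surface method encloses everything inside the endocardium —
#' papillary muscle included. At mask level that is the union of blood and
#' papillary masks with any remaining interior holes filled, per slice.
#'
#' @param blood logical blood-pool mask (2D matrix or 3D array
#'   \code{[row, col, slice]}).
#' @param papillary matching papillary mask; may be all-FALSE.
#' @return Filled mask of the same shape, logical.
#' @export
endocardialFill <- function(blood, papillary) {
  stopifnot(identical(dim(blood), dim(papillary)))
  fill2d <- function(b, p) EBImage::fillHull((b | p) * 1) > 0
  if (is.matrix(blood)) return(fill2d(blood != 0, papillary != 0))
  stopifnot(length(dim(blood)) == 3L)
  out <- array(FALSE, dim = dim(blood))
  for (sl in seq_len(dim(blood)[3L]))
    out[, , sl] <- fill2d(blood[, , sl] != 0, papillary[, , sl] != 0)
  out
}

#' Volume of the luminal (free-floating) papillary muscle
#'
#' Commercial contour software that segments papillary muscle automatically
#' only captures the part lying free in the lumen, not muscle directly
#' adjacent to the myocardial wall. This emulates that rule: per slice,
#' 4-connected papillary components having at least one pixel 4-adjacent to a
#' myocardium pixel are discarded; the remaining (luminal) areas are summed
#' into a Simpson volume.
#'
#' @param papillary logical papillary mask, 3D \code{[row, col, slice]} (or
#'   2D for a single slice).
#' @param myocardium matching myocardium mask.
#' @param geometry an \linkS4class{ImageGeometry}.
#' @param includeGap passed to [simpsonVolume()].
#' @return Volume in mL.
#' @export
luminalPapillaryVolume <- function(papillary, myocardium, geometry,
                                   includeGap = TRUE) {
  if (is.matrix(papillary)) {
    papillary <- array(papillary, c(dim(papillary), 1L))
    myocardium <- array(myocardium, c(dim(myocardium), 1L))
  }
  stopifnot(identical(dim(papillary), dim(myocardium)),
            length(dim(papillary)) == 3L)
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L)
  areas <- vapply(seq_len(dim(papillary)[3L]), function(sl) {
    p <- papillary[, , sl] != 0
    if (!any(p)) return(0)
    lab <- EBImage::bwlabel(p * 1)
    nearWall <- EBImage::dilate((myocardium[, , sl] != 0) * 1, cross) > 0
    attached <- unique(lab[lab > 0 & nearWall])
    luminal <- p & !(lab %in% attached)
    maskArea(matrix(luminal, nrow(p), ncol(p)), geometry)
  }, numeric(1))
  simpsonVolume(areas, geometry, includeGap)
}
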