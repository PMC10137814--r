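#' Read a 4D cine stack from NIfTI
#'
#' Expects a 4D NIfTI file with phases along the 4th dimension. In-plane
#' spacings and slice thickness come from the header pixdim; the inter-slice
#' gap is not representable in a plain NIfTI header and is supplied by the
#' caller (or a JSON sidecar written by [writeCine()]).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param gapFraction inter-slice gap as a fraction of slice thickness; if
#'   NULL, a sidecar `<path>.json` is consulted and 0 assumed otherwise.
#' @return A \linkS4class{CineStack}.
#' @export
readCine <- function(path, gapFraction = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI (row, col, slice, phase); got ", length(d),
         " dimensions. For 3D data supply the cine phase axis explicitly by ",
         "reshaping to 4D.")
  # NIfTI stores pixdim as float32; round to its significant precision so
  # clinical spacings like 1.8 mm come back exact
  pd <- signif(RNifti::pixdim(img), 6)
  if (any(pd[1:3] <= 0)) stop("non-positive voxel spacings in the header")
  if (is.null(gapFraction)) {
    sidecar <- paste0(path, ".json")
    gapFraction <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar)$gap_fraction else 0
  }
  geom <- imageGeometry(spacingRow = pd[1L], spacingCol = pd[2L],
                        sliceThickness = pd[3L], gapFraction = gapFraction,
                        nSlices = d[3L], nPhases = d[4L])
  cineStack(array(as.numeric(img), dim = d), geom)
}

#' Write a cine stack (or mask) as NIfTI
#'
#' Writes the 4D array with spacings in the header plus a JSON sidecar
#' carrying the gap fraction (NIfTI has no slot for it).
#'
#' @param stack a \linkS4class{CineStack}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeCine <- function(stack, path) {
  stopifnot(is(stack, "CineStack"))
  g <- geometry(stack)
  img <- RNifti::asNifti(intensities(stack))
  RNifti::pixdim(img) <- c(g@spacingRow, g@spacingCol, g@sliceThickness, 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(gap_fraction = g@gapFraction),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @describeIn writeCine Write a binary mask aligned to a geometry as uint8
#'   NIfTI.
#' @param mask logical 3D/4D array.
#' @param geometry the \linkS4class{ImageGeometry} of the source stack.
#' @export
writeMask <- function(mask, geometry, path) {
  arr <- array(as.integer(mask != 0), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry@spacingRow, geometry@spacingCol,
                           geometry@sliceThickness, 1)[seq_along(dim(mask))]
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @describeIn writeCine Read a mask written by [writeMask()] back as a
#'   logical array.
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' Brush-stroke JSON serialization
#'
#' The on-disk schema uses 0-based indices:
#' \code{{"radius": r, "phase": p, "positions": [[slice,row,col], ...],
#' "fixed_bounds": [lo, hi] | null}}. Indices are converted to R's 1-based
#' convention on read and back on write.
#'
#' @param stroke a \linkS4class{BrushStroke}.
#' @param path JSON file path.
#' @return [readBrushStroke()] returns a \linkS4class{BrushStroke};
#'   [writeBrushStroke()] returns the path invisibly.
#' @export
writeBrushStroke <- function(stroke, path) {
  stopifnot(is(stroke, "BrushStroke"))
  pos <- unname(lapply(seq_len(nrow(stroke@positions)), function(i)
    as.integer(stroke@positions[i, ] - 1L)))
  obj <- list(radius = stroke@radius,
              phase = stroke@phase - 1L,
              positions = pos,
              fixed_bounds = stroke@fixedBounds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname writeBrushStroke
#' @export
readBrushStroke <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- obj$positions
  if (is.null(pos) || length(pos) == 0L) {
    pos <- matrix(integer(), 0L, 3L)
  } else {
    if (!is.matrix(pos))
      pos <- matrix(as.integer(unlist(pos)), ncol = 3L, byrow = TRUE)
    pos <- pos + 1L
  }
  brushStroke(pos,
              radius = obj$radius,
              phase = (if (is.null(obj$phase)) 0L else obj$phase) + 1L,
              fixedBounds = obj$fixed_bounds)
}

#' Write function parameters as deterministic JSON
#'
#' Keys are sorted and EF is rendered in percent alongside the fractional
#' value, so downstream consumers never guess the scale.
#'
#' @param params a \linkS4class{FunctionParams}.
#' @param path JSON file path.
#' @export
writeParams <- function(params, path) {
  stopifnot(is(params, "FunctionParams"))
  obj <- list(edv_mL = params@edv, ef = params@ef,
              ef_pct = 100 * params@ef, esv_mL = params@esv,
              method = params@method, sv_mL = params@sv)
  obj <- obj[order(names(obj))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  computeFunctionParams(obj$edv_mL, obj$esv_mL, method = obj$method)
}

#' Write a cohort report as CSV + JSON
#'
#' @param report a \code{cohortReport} from [buildCohortReport()].
#' @param prefix output path prefix; writes `<prefix>_summary.csv`,
#'   `<prefix>_tost.csv` (when present) and `<prefix>.json`.
#' @return Character vector of written paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
  stopifnot(inherits(report, "cohortReport"))
  paths <- character()
  p <- paste0(prefix, "_summary.csv")
  utils::write.csv(report$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$tost)) {
    p <- paste0(prefix, "_tost.csv")
    utils::write.csv(report$tost, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(reference = report$reference,
         summary = report$summary,
         tost = report$tost,
         flagged = report$flagged),
    p, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
  paths <- c(paths, p)
  invisible(paths)
}
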