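#' Construct a scripted brush stroke
#'
#' @param positions integer matrix (or data.frame) with one row per cursor
#'   position and columns (slice, row, col), 1-based.
#' @param radius brush radius in pixels.
#' @param phase 1-based cine phase the stroke annotates (default 1 = ED).
#' @param fixedBounds optional numeric (lo, hi) intensity pair overriding the
#'   locally derived bounds; NULL (default) derives bounds per position.
#' @return A \linkS4class{BrushStroke}.
#' @export
brushStroke <- function(positions, radius = 4, phase = 1L,
                        fixedBounds = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L)
    positions <- matrix(integer(), 0L, 3L)
  storage.mode(positions) <- "integer"
  colnames(positions) <- c("slice", "row", "col")
  new("BrushStroke", positions = positions, radius = as.numeric(radius),
      phase = as.integer(phase),
      fixedBounds = if (is.null(fixedBounds)) NULL else as.numeric(fixedBounds))
}

# (drow, dcol) offsets of pixel centres within Euclidean distance `radius`
.diskOffsets <- function(radius) {
  r <- ceiling(radius)
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d <- d[d$dr^2 + d$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(d)
}

# in-bounds (row, col) index matrix of the brush disk at `position`
.diskPixels <- function(dimImg, position, offsets) {
  rr <- position[1L] + offsets[, 1L]
  cc <- position[2L] + offsets[, 2L]
  keep <- rr >= 1L & rr <= dimImg[1L] & cc >= 1L & cc <= dimImg[2L]
  cbind(row = rr[keep], col = cc[keep])
}

#' Local intensity statistics in a brush neighbourhood
#'
#' Computes minimum, maximum, mean and (population) variance of the image
#' intensities whose pixel centres lie within `radius` pixels of `position`
#' (Euclidean distance), clipped to the image bounds. These statistics drive
#' the threshold derivation of [deriveBounds()].
#'
#' @param image 2D numeric matrix (one slice of a cine stack).
#' @param position integer (row, col), 1-based, inside the image.
#' @param radius brush radius in pixels.
#' @return A \linkS4class{LocalStats}.
#' @examples
#' img <- matrix(100, 5, 5)
#' computeLocalStats(img, c(3, 3), 2)
#' @export
computeLocalStats <- function(image, position, radius) {
  stopifnot(is.matrix(image), radius >= 1)
  position <- as.integer(position)
  if (position[1L] < 1L || position[1L] > nrow(image) ||
      position[2L] < 1L || position[2L] > ncol(image))
    stop("position lies outside the image")
  px <- .diskPixels(dim(image), position, .diskOffsets(radius))
  v <- image[px]
  m <- mean(v)
  new("LocalStats", minimum = min(v), maximum = max(v), mean = m,
      variance = mean((v - m)^2), n = length(v))
}

#' Derive region-growing intensity bounds from local statistics
#'
#' The interval is mean +/- k standard deviations, clipped to the observed
#' local minimum and maximum: \code{lo = max(min, mean - k*sqrt(var))},
#' \code{hi = min(max, mean + k*sqrt(var))}. A supplied \code{fixedBounds}
#' pair overrides the derived interval entirely, emulating the fixed
#' intensity thresholds the brush tool optionally accepts.
#'
#' @param stats a \linkS4class{LocalStats}.
#' @param k half-width of the interval in local standard deviations
#'   (default 2).
#' @param fixedBounds optional numeric (lo, hi) override.
#' @return Numeric (lo, hi).
#' @examples
#' s <- new("LocalStats", minimum = 100, maximum = 200, mean = 180,
#'          variance = 400, n = 25L)
#' deriveBounds(s, k = 2)  # c(140, 200)
#' @export
deriveBounds <- function(stats, k = 2, fixedBounds = NULL) {
  if (!is.null(fixedBounds)) {
    stopifnot(length(fixedBounds) == 2L, fixedBounds[1L] <= fixedBounds[2L])
    return(as.numeric(fixedBounds))
  }
  stopifnot(is(stats, "LocalStats"), k > 0)
  sdv <- sqrt(stats@variance)
  c(max(stats@minimum, stats@mean - k * sdv),
    min(stats@maximum, stats@mean + k * sdv))
}

#' Seed-constrained region growing within a brush disk
#'
#' Returns the 4-connected component, within the brush disk, of the pixels
#' whose intensity lies in \code{[lo, hi]} that contains the seed. A seed
#' whose own intensity falls outside the bounds yields an empty mask with a
#' warning — the signal that the user painted non-target tissue.
#'
#' @param image 2D numeric matrix.
#' @param seed integer (row, col), 1-based.
#' @param bounds numeric (lo, hi) intensity interval.
#' @param brushDisk integer matrix of in-bounds (row, col) disk pixels; grown
#'   pixels are confined to this set. Defaults to the whole image.
#' @return Logical matrix of the same size as `image`.
#' @export
regionGrow <- function(image, seed, bounds,
                       brushDisk = as.matrix(expand.grid(
                         row = seq_len(nrow(image)),
                         col = seq_len(ncol(image))))) {
  stopifnot(is.matrix(image), length(bounds) == 2L)
  seed <- as.integer(seed)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  sInt <- image[seed[1L], seed[2L]]
  if (is.na(sInt) || sInt < bounds[1L] || sInt > bounds[2L]) {
    warning("seed intensity outside bounds; returning an empty mask")
    return(mask)
  }
  inDisk <- matrix(FALSE, nrow(image), ncol(image))
  inDisk[brushDisk] <- TRUE
  if (!inDisk[seed[1L], seed[2L]])
    stop("seed must lie within the brush disk")
  eligible <- inDisk & image >= bounds[1L] & image <= bounds[2L]

  # iterative 4-connected flood fill
  nR <- nrow(image)
  queue <- integer(sum(eligible))
  queue[1L] <- (seed[2L] - 1L) * nR + seed[1L]
  mask[queue[1L]] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    r <- ((idx - 1L) %% nR) + 1L
    cc <- ((idx - 1L) %/% nR) + 1L
    for (nb in list(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))) {
      if (nb[1L] < 1L || nb[1L] > nR || nb[2L] < 1L || nb[2L] > ncol(image))
        next
      ni <- (nb[2L] - 1L) * nR + nb[1L]
      if (eligible[ni] && !mask[ni]) {
        mask[ni] <- TRUE
        tail <- tail + 1L
        queue[tail] <- ni
      }
    }
  }
  mask
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk-shaped structuring element,
#' applied per slice in 2D. Closing fills pixel-scale holes and notches that
#' image noise punches into the grown region; the default 1-pixel element
#' (a 3x3 box) is deliberately small so papillary muscles and the myocardium
#' are never bridged.
#'
#' The element is the set of pixels within Euclidean distance `elementRadius`
#' of the centre — the same disk definition as the brush — so radius 1 is the
#' 4-neighbourhood plus shape.
#'
#' @param mask logical/binary matrix, or a 3D/4D array closed slice-wise.
#' @param elementRadius radius of the structuring element in pixels.
#' @return Mask of the same shape, logical.
#' @export
applyClosing <- function(mask, elementRadius = 1) {
  r <- ceiling(elementRadius)
  offs <- .diskOffsets(elementRadius)
  kern <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  kern[cbind(offs[, 1L] + r + 1L, offs[, 2L] + r + 1L)] <- 1
  close2d <- function(m) {
    # pad so closing behaves as if the image continued as background
    p <- as.integer(elementRadius) + 1L
    mp <- matrix(0, nrow(m) + 2L * p, ncol(m) + 2L * p)
    mp[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m * 1
    out <- EBImage::closing(mp, kern)
    out[p + seq_len(nrow(m)), p + seq_len(ncol(m))] > 0
  }
  d <- dim(mask)
  if (length(d) == 2L) return(close2d(mask))
  out <- array(FALSE, dim = d)
  if (length(d) == 3L) {
    for (s in seq_len(d[3L])) out[, , s] <- close2d(mask[, , s])
  } else if (length(d) == 4L) {
    for (t in seq_len(d[4L])) for (s in seq_len(d[3L]))
      out[, , s, t] <- close2d(mask[, , s, t])
  } else stop("mask must be 2D, 3D or 4D")
  out
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same Euclidean-disk element as
#' [applyClosing()], applied per slice. Opening removes isolated noise pixels
#' (e.g. from thresholding a noisy image into tissue-evidence masks) while
#' preserving solid regions; use it to clean masks fed to
#' [detectBasalSlice()].
#'
#' @param mask logical/binary matrix, or a 3D/4D array opened slice-wise.
#' @param elementRadius radius of the structuring element in pixels.
#' @return Mask of the same shape, logical.
#' @export
cleanMask <- function(mask, elementRadius = 1) {
  r <- ceiling(elementRadius)
  offs <- .diskOffsets(elementRadius)
  kern <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  kern[cbind(offs[, 1L] + r + 1L, offs[, 2L] + r + 1L)] <- 1
  open2d <- function(m) EBImage::opening(m * 1, kern) > 0
  d <- dim(mask)
  if (length(d) == 2L) return(open2d(mask))
  out <- array(FALSE, dim = d)
  if (length(d) == 3L) {
    for (s in seq_len(d[3L])) out[, , s] <- open2d(mask[, , s])
  } else if (length(d) == 4L) {
    for (t in seq_len(d[4L])) for (s in seq_len(d[3L]))
      out[, , s, t] <- open2d(mask[, , s, t])
  } else stop("mask must be 2D, 3D or 4D")
  out
}

#' Segment a cine stack from a scripted brush stroke
#'
#' The headless pixel-based brush: for every cursor position, local intensity
#' statistics are computed under the brush ([computeLocalStats()]), turned
#' into intensity bounds ([deriveBounds()], unless the stroke carries fixed
#' bounds), and a seed-constrained region growing confined to that position's
#' brush disk is run ([regionGrow()]). The union over all positions is then
#' cleaned up by a per-slice morphological closing ([applyClosing()]).
#'
#' @param stack a \linkS4class{CineStack}.
#' @param stroke a \linkS4class{BrushStroke}; its \code{phase} selects the
#'   cine phase that is segmented.
#' @param k bounds half-width in local standard deviations.
#' @param closingRadius structuring-element radius for the closing; 0 skips
#'   the closing.
#' @return Logical 3D array \code{[row, col, slice]} for the stroke's phase.
#' @export
segmentStroke <- function(stack, stroke, k = 2, closingRadius = 1) {
  stopifnot(is(stack, "CineStack"), is(stroke, "BrushStroke"))
  img4 <- intensities(stack)
  d <- dim(img4)
  mask <- array(FALSE, dim = d[1:3])
  if (nrow(stroke@positions) == 0L) return(mask)
  if (stroke@phase > d[4L])
    stop("stroke phase exceeds the number of cine phases")
  if (any(stroke@positions[, 1L] > d[3L]) ||
      any(stroke@positions[, 2L] > d[1L]) ||
      any(stroke@positions[, 3L] > d[2L]))
    stop("stroke positions lie outside the image bounds")

  offs <- .diskOffsets(stroke@radius)
  for (sl in unique(stroke@positions[, 1L])) {
    img <- img4[, , sl, stroke@phase]
    sliceMask <- matrix(FALSE, d[1L], d[2L])
    rows <- which(stroke@positions[, 1L] == sl)
    for (i in rows) {
      pos <- stroke@positions[i, 2:3]
      disk <- .diskPixels(dim(img), pos, offs)
      bounds <- if (is.null(stroke@fixedBounds)) {
        deriveBounds(computeLocalStats(img, pos, stroke@radius), k = k)
      } else stroke@fixedBounds
      sliceMask <- sliceMask | regionGrow(img, pos, bounds, disk)
    }
    if (closingRadius > 0)
      sliceMask <- applyClosing(sliceMask, closingRadius)
    mask[, , sl] <- sliceMask
  }
  mask
}

#' Script a brush stroke from a mask
#'
#' Builds the scripted equivalent of a user roughly colouring a region:
#' cursor positions are taken on a regular grid over the pixels of `mask`
#' (optionally eroded first so positions keep away from the boundary). Used
#' to drive [segmentStroke()] on phantoms where the target region is known.
#'
#' @param mask logical 3D array \code{[row, col, slice]} (or 2D matrix) of the
#'   region to paint.
#' @param radius brush radius in pixels.
#' @param step grid step between cursor positions, pixels.
#' @param phase 1-based phase recorded in the stroke.
#' @param fixedBounds optional fixed intensity bounds stored in the stroke.
#' @param erode erosion radius (pixels) applied to the mask before placing
#'   positions; 0 paints right up to the boundary.
#' @return A \linkS4class{BrushStroke}.
#' @export
strokeFromMask <- function(mask, radius = 4, step = 2, phase = 1L,
                           fixedBounds = NULL, erode = 0) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  stopifnot(length(dim(mask)) == 3L)
  pos <- NULL
  for (sl in seq_len(dim(mask)[3L])) {
    m <- mask[, , sl]
    if (!any(m)) next
    if (erode > 0)
      m <- EBImage::erode(m * 1, EBImage::makeBrush(2L * as.integer(erode) + 1L,
                                                    "disc")) > 0
    idx <- which(m, arr.ind = TRUE)
    keep <- idx[, 1L] %% step == 0L & idx[, 2L] %% step == 0L
    if (any(keep))
      pos <- rbind(pos, cbind(sl, idx[keep, 1L], idx[keep, 2L]))
  }
  if (is.null(pos)) pos <- matrix(integer(), 0L, 3L)
  brushStroke(pos, radius = radius, phase = phase, fixedBounds = fixedBounds)
}
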