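#' Construct phantom parameters
#'
#' Defaults describe a realistic adult left ventricle imaged with the protocol
#' of [imageGeometry()]: end-diastolic endocardial semi-axes 34 x 28 mm at the
#' base tapering as a half-ellipsoid toward the apex, a 10 mm end-diastolic
#' wall that thickens during systole so myocardial mass is conserved, a target
#' ejection fraction of 0.55 reached at phase 11 of 25 along a cosine volume
#' curve, and two 7 mm papillary bodies (one free in the lumen, one pressed
#' into the wall) spanning the mid-ventricle. Intensities emulate bright-blood
#' SSFP contrast (blood 400, myocardium 120, background 40 a.u.) with additive
#' Gaussian noise of 5% of the blood intensity.
#'
#' @param nRow,nCol image matrix (default 192 x 109).
#' @param radiusRow,radiusCol basal end-diastolic endocardial semi-axes, mm.
#' @param wallThickness end-diastolic wall thickness, mm.
#' @param ef target true-blood-pool ejection fraction, fraction in (0, 1).
#' @param esPhase 1-based end-systolic phase.
#' @param papillary data.frame with columns \code{angle} (deg),
#'   \code{radialFrac}, \code{radius} (mm), \code{attached} (logical); use a
#'   zero-row data.frame for a phantom without papillary muscle.
#' @param papillarySpan fractions of the LV stack depth the bodies span.
#' @param papillaryTwist angular drift of the bodies per slice, degrees;
#'   papillary muscles insert obliquely rather than as straight vertical
#'   columns.
#' @param bloodIntensity,myoIntensity,backgroundIntensity mean intensities
#'   (arbitrary units); blood must exceed myocardium.
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param basalArcDeg angular extent of the open myocardial arc on the atrial
#'   transition slice (< 180 so the 50% basal rule rejects it).
#' @param oversample linear truth-rasterization oversampling factor (>= 4).
#' @return A \linkS4class{PhantomParams}.
#' @export
phantomParams <- function(nRow = 192L, nCol = 109L,
                          radiusRow = 34, radiusCol = 28,
                          wallThickness = 10,
                          ef = 0.55, esPhase = 11L,
                          papillary = data.frame(
                            angle = c(20, 200),
                            radialFrac = c(0.3, NA),
                            radius = c(7, 7),
                            attached = c(FALSE, TRUE)),
                          papillarySpan = c(0.08, 0.58),
                          papillaryTwist = 8,
                          bloodIntensity = 400, myoIntensity = 120,
                          backgroundIntensity = 40,
                          noiseSd = 20,
                          basalArcDeg = 144,
                          oversample = 4L) {
  new("PhantomParams",
      nRow = as.integer(nRow), nCol = as.integer(nCol),
      radiusRow = as.numeric(radiusRow), radiusCol = as.numeric(radiusCol),
      wallThickness = as.numeric(wallThickness),
      ef = as.numeric(ef), esPhase = as.integer(esPhase),
      papillary = papillary, papillarySpan = as.numeric(papillarySpan),
      papillaryTwist = as.numeric(papillaryTwist),
      bloodIntensity = as.numeric(bloodIntensity),
      myoIntensity = as.numeric(myoIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSd = as.numeric(noiseSd),
      basalArcDeg = as.numeric(basalArcDeg),
      oversample = as.integer(oversample))
}

# mm overlap by which a wall-attached papillary body is pressed past the
# endocardial border, guaranteeing pixel adjacency to the myocardium
.attachOverlap <- 1.5

# area of the circular segment of a circle of radius r cut off beyond a chord
# at distance h from the centre (h in [0, r])
.segmentArea <- function(r, h) {
  r^2 * acos(h / r) - h * sqrt(r^2 - h^2)
}

# endocardial radius of the ellipse (A, B) along direction theta (radians)
.ellipseRadius <- function(A, B, theta) {
  1 / sqrt((cos(theta) / A)^2 + (sin(theta) / B)^2)
}

# cosine contraction weight: 0 at phase 1 (ED), 1 at esPhase, cyclically back
.contractionWeight <- function(phase, esPhase, nPhases) {
  ifelse(phase <= esPhase,
         (1 - cos(pi * (phase - 1) / (esPhase - 1))) / 2,
         (1 - cos(pi * (nPhases + 1 - phase) / (nPhases + 1 - esPhase))) / 2)
}

# papillary body centres (mm) for an endocardial ellipse (A, B); matrix with
# one row per body, columns cx, cy; NULL if no bodies. `twistDeg` rotates the
# insertion angle (oblique course of the muscle down the stack).
.papCentres <- function(pap, A, B, twistDeg = 0) {
  if (nrow(pap) == 0L) return(NULL)
  th <- (pap$angle + twistDeg) * pi / 180
  rho <- .ellipseRadius(A, B, th)
  cdist <- ifelse(pap$attached, rho - pap$radius + .attachOverlap,
                  pap$radialFrac * rho)
  cbind(cx = cdist * cos(th), cy = cdist * sin(th))
}

#' Generate a ground-truthed synthetic cine phantom
#'
#' Builds a 4D short-axis cine stack of a contracting left ventricle together
#' with exact ground truth. The LV is a stack of concentric endo-/epicardial
#' ellipses tapering as a half-ellipsoid toward the apex; slice 1 is the
#' atrial transition, carrying a bright pool and an open myocardial arc so the
#' basal-slice rule has something to reject. In-plane radii follow a cosine
#' volume curve scaled so the true blood pool achieves the requested ejection
#' fraction; the wall thickens during systole to conserve myocardial ring
#' area (mass). Papillary bodies are cylinders of known volume; parts of an
#' attached body inside the wall count as myocardium, so the papillary truth
#' is the luminal muscle a contour would enclose.
#'
#' Truth volumes are obtained by counting sub-pixels on an `oversample`-times
#' finer grid than the image, so they are (nearly) independent of the native
#' rasterization that the segmentation sees.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @param geometry an \linkS4class{ImageGeometry}.
#' @param seed integer seed fixing the noise; identical seeds give
#'   bit-identical output.
#' @return A list with elements \code{stack} (\linkS4class{CineStack}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @examples
#' ph <- generatePhantom(phantomParams(noiseSd = 0), imageGeometry(), seed = 1)
#' ph$truth
#' @export
generatePhantom <- function(params = phantomParams(),
                            geometry = imageGeometry(), seed = 1L) {
  stopifnot(is(params, "PhantomParams"), is(geometry, "ImageGeometry"))
  validObject(params); validObject(geometry)
  set.seed(as.integer(seed))

  nR <- params@nRow; nC <- params@nCol
  nS <- geometry@nSlices; nP <- geometry@nPhases
  dz <- sliceSpacing(geometry, includeGap = TRUE)
  pap <- params@papillary
  os <- params@oversample

  # LV occupies slices 2..nS; slice 1 is the atrial transition
  basal <- 2L
  nLV <- nS - basal + 1L
  u <- (seq_len(nLV) - 0.5) / nLV          # normalized long-axis depth
  taper <- sqrt(pmax(0, 1 - u^2))
  aED <- params@radiusRow * taper
  bED <- params@radiusCol * taper

  # papillary span in LV-slice terms
  spanSel <- u >= params@papillarySpan[1L] & u <= params@papillarySpan[2L]
  nSpan <- sum(spanSel)

  # analytic volumes drive the contraction curve (mm^3)
  E0 <- sum(pi * aED * bED) * dz
  papArea <- if (nrow(pap) == 0L) 0 else
    sum(ifelse(pap$attached,
               pi * pap$radius^2 -
                 .segmentArea(pap$radius, pap$radius - .attachOverlap),
               pi * pap$radius^2))
  P0 <- papArea * nSpan * dz
  B0 <- E0 - P0
  if (B0 <= 0)
    stop("papillary bodies exceed the cavity volume; shrink them")
  Ees <- B0 * (1 - params@ef) + P0
  cw <- .contractionWeight(seq_len(nP), params@esPhase, nP)
  sFac <- sqrt((E0 - (E0 - Ees) * cw) / E0)

  # wall thickness per slice/phase conserving the ED ring area
  Cring <- params@wallThickness^2 + params@wallThickness * (aED + bED)

  # confirm the ventricle fits the matrix (largest epicardial extent)
  wMax <- (-(aED[1L] + bED[1L]) * min(sFac) +
           sqrt(((aED[1L] + bED[1L]) * min(sFac))^2 + 4 * Cring[1L])) / 2
  maxExtR <- aED[1L] + wMax + 2 * geometry@spacingRow
  maxExtC <- bED[1L] + wMax + 2 * geometry@spacingCol
  if (maxExtR > nR * geometry@spacingRow / 2 ||
      maxExtC > nC * geometry@spacingCol / 2)
    stop("geometry too small to contain the ventricle: enlarge the matrix ",
         "or shrink the ventricle radii/wall")

  # pixel-centre coordinates in mm, origin at the image centre
  xs <- (seq_len(nR) - (nR + 1) / 2) * geometry@spacingRow
  ys <- (seq_len(nC) - (nC + 1) / 2) * geometry@spacingCol
  X <- matrix(xs, nR, nC)
  Y <- matrix(ys, nR, nC, byrow = TRUE)

  intens <- array(params@backgroundIntensity, dim = c(nR, nC, nS, nP))
  blood <- array(FALSE, dim = c(nR, nC, nS, nP))
  papM <- array(FALSE, dim = c(nR, nC, nS, nP))
  myo <- array(FALSE, dim = c(nR, nC, nS, nP))

  volumes <- data.frame(phase = seq_len(nP), blood_mL = 0,
                        papillary_mL = 0, papillary_luminal_mL = 0,
                        papillary_wall_mL = 0, myocardium_mL = 0)

  # oversampled sub-pixel grid over the ventricular bounding box
  halfR <- ceiling(maxExtR / geometry@spacingRow) + 1L
  halfC <- ceiling(maxExtC / geometry@spacingCol) + 1L
  rIdx <- max(1L, round(nR / 2) - halfR):min(nR, round(nR / 2) + halfR)
  cIdx <- max(1L, round(nC / 2) - halfC):min(nC, round(nC / 2) + halfC)
  sub <- (seq_len(os) - 0.5) / os - 0.5
  xo <- as.vector(outer(sub * geometry@spacingRow, xs[rIdx], `+`))
  yo <- as.vector(outer(sub * geometry@spacingCol, ys[cIdx], `+`))
  XO <- matrix(xo, length(xo), length(yo))
  YO <- matrix(yo, length(xo), length(yo), byrow = TRUE)
  subArea <- geometry@spacingRow * geometry@spacingCol / os^2

  inPap <- function(PX, PY, centres, sel) {
    hit <- matrix(FALSE, nrow(PX), ncol(PX))
    if (is.null(centres)) return(hit)
    for (k in which(sel)) {
      hit <- hit | ((PX - centres[k, 1L])^2 + (PY - centres[k, 2L])^2 <=
                      pap$radius[k]^2)
    }
    hit
  }

  for (t in seq_len(nP)) {
    s <- sFac[t]
    for (j in seq_len(nLV)) {
      sl <- basal + j - 1L
      A <- aED[j] * s; B <- bED[j] * s
      if (A <= 0 || B <= 0) next
      w <- (-(A + B) + sqrt((A + B)^2 + 4 * Cring[j])) / 2
      ctr <- .papCentres(pap, A, B,
                         twistDeg = params@papillaryTwist * (j - mean(which(spanSel))))
      onSpan <- if (nrow(pap) > 0L && spanSel[j]) !logical(nrow(pap)) else
        logical(max(1L, nrow(pap)))

      endo <- (X / A)^2 + (Y / B)^2 <= 1
      epi <- (X / (A + w))^2 + (Y / (B + w))^2 <= 1
      papHit <- inPap(X, Y, ctr, onSpan) & endo
      bl <- endo & !papHit
      my <- epi & !endo

      blood[, , sl, t] <- bl
      papM[, , sl, t] <- papHit
      myo[, , sl, t] <- my
      slc <- intens[, , sl, t]
      slc[my | papHit] <- params@myoIntensity
      slc[bl] <- params@bloodIntensity
      intens[, , sl, t] <- slc

      # oversampled truth areas
      endoO <- (XO / A)^2 + (YO / B)^2 <= 1
      epiO <- (XO / (A + w))^2 + (YO / (B + w))^2 <= 1
      lumO <- inPap(XO, YO, ctr, onSpan & !pap$attached) & endoO
      attO <- inPap(XO, YO, ctr, onSpan & pap$attached) & endoO & !lumO
      volumes$blood_mL[t] <- volumes$blood_mL[t] +
        sum(endoO & !lumO & !attO) * subArea
      volumes$papillary_luminal_mL[t] <- volumes$papillary_luminal_mL[t] +
        sum(lumO) * subArea
      volumes$papillary_wall_mL[t] <- volumes$papillary_wall_mL[t] +
        sum(attO) * subArea
      volumes$myocardium_mL[t] <- volumes$myocardium_mL[t] +
        sum(epiO & !endoO) * subArea
    }

    # atrial transition slice: bright pool + open myocardial arc (not truth)
    A1 <- aED[1L]; B1 <- bED[1L]; w1 <- params@wallThickness
    pool <- (X / A1)^2 + (Y / B1)^2 <= 1
    ring <- ((X / (A1 + w1))^2 + (Y / (B1 + w1))^2 <= 1) & !pool
    ang <- atan2(Y, X) * 180 / pi
    arc <- ring & ang >= -params@basalArcDeg / 2 & ang <= params@basalArcDeg / 2
    slc <- intens[, , 1L, t]
    slc[arc] <- params@myoIntensity
    slc[pool] <- params@bloodIntensity
    intens[, , 1L, t] <- slc
  }

  volCols <- c("blood_mL", "papillary_luminal_mL", "papillary_wall_mL",
               "myocardium_mL")
  volumes[volCols] <- lapply(volumes[volCols], function(v) v * dz / 1000)
  volumes$papillary_mL <- volumes$papillary_luminal_mL +
    volumes$papillary_wall_mL

  if (params@noiseSd > 0) {
    intens <- intens + array(stats::rnorm(length(intens), 0, params@noiseSd),
                             dim = dim(intens))
    intens[intens < 0] <- 0
  }

  stack <- cineStack(intens, geometry)
  truth <- new("PhantomTruth",
               volumes = volumes,
               bloodMask = blood, papillaryMask = papM, myocardiumMask = myo,
               basalSlice = basal, edPhase = 1L,
               esPhase = params@esPhase)
  list(stack = stack, truth = truth)
}
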