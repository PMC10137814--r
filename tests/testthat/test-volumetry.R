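test_that("mask areas are pixel counts times pixel area", {
  g <- imageGeometry(1.8, 2.5, 8)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(maskArea(m, g), 450)
  expect_equal(maskArea(matrix(FALSE, 5, 5), g), 0)
  expect_equal(maskArea(matrix(TRUE, 192, 109), g), 94176)
})

test_that("Simpson volumes sum areas times slice spacing", {
  expect_equal(simpsonVolume(1000, imageGeometry(1, 1, 8, gapFraction = 0)), 8)
  expect_equal(simpsonVolume(rep(1500, 10),
                             imageGeometry(1.8, 2.5, 8, gapFraction = 0.1)),
               132)
  expect_equal(simpsonVolume(numeric(0), imageGeometry()), 0)
  expect_error(simpsonVolume(c(100, -1), imageGeometry()), "non-negative")
})

test_that("Simpson volume is additive over slice partitions", {
  set.seed(3)
  areas <- runif(12, 0, 2000)
  g <- imageGeometry()
  whole <- simpsonVolume(areas, g)
  expect_equal(simpsonVolume(areas[1:5], g) + simpsonVolume(areas[6:12], g),
               whole)
})

test_that("ring coverage follows the angular extent of the myocardial arc", {
  g <- imageGeometry(1, 1, 8)  # isotropic pixels keep angles undistorted
  blood <- ellipseMask(41, 41, c(21, 21), 8, 8)
  full <- arcMask(41, 41, c(21, 21), 10, 14)
  expect_equal(ringCoverage(full, blood, g), 1.0)
  half <- arcMask(41, 41, c(21, 21), 10, 14, from = -90, to = 90)
  expect_lt(abs(ringCoverage(half, blood, g) - 0.5), 0.02)
  arc <- arcMask(41, 41, c(21, 21), 10, 14, from = -60, to = 60)
  expect_lt(abs(ringCoverage(arc, blood, g) - 1 / 3), 0.03)
})

test_that("the basal slice is the first one with a half-closed ring", {
  g <- imageGeometry(1, 1, 8)
  blood <- ellipseMask(41, 41, c(21, 21), 8, 8)
  myo <- array(FALSE, c(41, 41, 3))
  bl <- array(FALSE, c(41, 41, 3))
  bl[, , 1:3] <- blood
  myo[, , 1] <- arcMask(41, 41, c(21, 21), 10, 14, from = -60, to = 60)
  myo[, , 2] <- arcMask(41, 41, c(21, 21), 10, 14, from = -92, to = 92)
  myo[, , 3] <- arcMask(41, 41, c(21, 21), 10, 14)
  expect_equal(detectBasalSlice(myo, bl, g), 2L)
  # nothing qualifies -> explicit error
  open <- myo; open[, , 2:3] <- myo[, , 1]
  expect_error(detectBasalSlice(open, bl, g), "base")
})

test_that("phase selection takes the first image as ED, area argmin as ES", {
  mk <- function(areas) {
    m <- array(FALSE, c(20, 20, 3, length(areas)))
    for (t in seq_along(areas))
      if (areas[t] > 0) m[seq_len(areas[t]), 1, 2, t] <- TRUE
    m
  }
  expect_equal(unname(selectPhases(mk(c(10, 6, 3, 7)), 2L)), c(1L, 3L))
  expect_equal(unname(selectPhases(mk(c(5, 5)), 2L)), c(1L, 1L))       # tie
  expect_equal(unname(selectPhases(mk(c(9, 7, 5, 3)), 2L)), c(1L, 4L)) # monotone
  expect_error(selectPhases(mk(c(0, 0)), 2L), "empty")
  # on the phantom, selection from intensities recovers the configured ES
  ph <- defaultPhantom()
  mid <- midThirdSlice(ph$truth@basalSlice, geometry(ph$stack)@nSlices)
  expect_equal(unname(selectPhases(ph$stack, mid, threshold = 260)),
               c(1L, ph$truth@esPhase))
})

test_that("function parameters satisfy the SV and EF identities", {
  fp <- computeFunctionParams(100, 50)
  expect_equal(fp@sv, 50)
  expect_equal(fp@ef, 0.5)
  fp <- computeFunctionParams(177, 87)
  expect_equal(fp@sv, 90)
  expect_equal(fp@ef, 90 / 177)       # ~50.8%
  fp <- computeFunctionParams(120, 120)
  expect_equal(fp@sv, 0)
  expect_equal(fp@ef, 0)
  expect_error(computeFunctionParams(0, 0), "positive")
  expect_error(computeFunctionParams(80, 90), "mislabelled")
})

test_that("EF is invariant under uniform area scaling", {
  set.seed(8)
  areas <- runif(10, 500, 2000)
  g <- imageGeometry()
  esAreas <- areas * 0.4
  ef1 <- with(list(edv = simpsonVolume(areas, g),
                   esv = simpsonVolume(esAreas, g)),
              computeFunctionParams(edv, esv)@ef)
  ef2 <- with(list(edv = simpsonVolume(3 * areas, g),
                   esv = simpsonVolume(3 * esAreas, g)),
              computeFunctionParams(edv, esv)@ef)
  expect_equal(ef1, ef2)
})

test_that("apical termination drops empty slices below the last filled one", {
  g <- imageGeometry(1, 1, 10, gapFraction = 0, nSlices = 5)
  m <- array(FALSE, c(10, 10, 5))
  m[1:5, 1:5, 2] <- TRUE   # 25 px
  m[1:5, 1:2, 3] <- TRUE   # 10 px
  # slices 4-5 empty below the last non-empty slice: excluded
  expect_equal(phaseVolume(m, g, basalSlice = 2L), (25 + 10) * 10 / 1000)
  # slices before the basal slice are excluded too
  m[1:3, 1:3, 1] <- TRUE
  expect_equal(phaseVolume(m, g, basalSlice = 2L), (25 + 10) * 10 / 1000)
})
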