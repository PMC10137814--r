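test_that("local stats match direct enumeration over the brush disk", {
  # constant field
  s <- computeLocalStats(matrix(100, 7, 7), c(4, 4), 2)
  expect_equal(s@minimum, 100)
  expect_equal(s@maximum, 100)
  expect_equal(s@mean, 100)
  expect_equal(s@variance, 0)

  # one outlier among constants, radius covering the whole 5x5 image
  img <- matrix(100, 5, 5)
  img[2, 4] <- 200
  s <- computeLocalStats(img, c(3, 3), 10)
  v <- as.vector(img)  # brute force over all 25 pixels
  expect_equal(s@n, 25L)
  expect_equal(s@minimum, 100)
  expect_equal(s@maximum, 200)
  expect_equal(s@mean, mean(v))
  expect_equal(s@variance, mean((v - mean(v))^2))

  # radius 1 at a corner clips to the in-bounds subset (3 pixels)
  img <- matrix(seq_len(25), 5, 5)
  s <- computeLocalStats(img, c(1, 1), 1)
  v <- c(img[1, 1], img[2, 1], img[1, 2])
  expect_equal(s@n, 3L)
  expect_equal(s@mean, mean(v))

  expect_error(computeLocalStats(img, c(0, 3), 1), "outside")
})

test_that("bounds are mean +/- k sd clipped to the local extrema", {
  sv <- function(mn, mx, m, va) new("LocalStats", minimum = mn, maximum = mx,
                                    mean = m, variance = va, n = 25L)
  expect_equal(deriveBounds(sv(50, 150, 100, 0), k = 2), c(100, 100))
  expect_equal(deriveBounds(sv(100, 200, 180, 400), k = 2), c(140, 200))
  expect_equal(deriveBounds(sv(100, 200, 180, 400), k = 2,
                            fixedBounds = c(150, 500)), c(150, 500))
})

test_that("region growing returns the seed's in-bounds connected component", {
  # two bright blobs separated by a dark column: only the seeded one grows
  img <- matrix(0, 9, 9)
  img[2:4, 2:4] <- 100
  img[6:8, 6:8] <- 100
  m <- regionGrow(img, c(3, 3), c(50, 150))
  expect_true(all(m[2:4, 2:4]))
  expect_false(any(m[6:8, 6:8]))

  # bright pool with an embedded dark spot: spot excluded (flood-fill oracle)
  set.seed(5)
  img <- matrix(300, 15, 15)
  img[7:9, 7:8] <- 80
  img <- img + matrix(rnorm(225, 0, 5), 15, 15)
  bounds <- c(200, 400)
  m <- regionGrow(img, c(2, 2), bounds)
  expect_identical(m, floodFillOracle(img >= 200 & img <= 400, c(2, 2)))
  expect_false(any(m[7:9, 7:8]))

  # unconstrained bounds over the whole image grow everywhere
  expect_true(all(regionGrow(img, c(1, 1), c(0, Inf))))

  # a seed painted on out-of-bounds tissue yields an empty mask + warning
  expect_warning(m0 <- regionGrow(img, c(8, 8), c(200, 400)), "outside")
  expect_false(any(m0))
})

test_that("region growing respects the brush disk", {
  img <- matrix(100, 21, 21)
  disk <- pixelLV:::.diskPixels(dim(img), c(11, 11),
                                pixelLV:::.diskOffsets(3))
  m <- regionGrow(img, c(11, 11), c(0, 200), disk)
  expect_equal(sum(m), nrow(disk))
  expect_false(any(m[1, ]))
})

test_that("closing fills pixel holes, fixes convex sets, is idempotent", {
  disk <- ellipseMask(21, 21, c(11, 11), 6, 6)
  expect_identical(applyClosing(disk, 1), disk)
  holed <- disk
  holed[11, 11] <- FALSE
  expect_identical(applyClosing(holed, 1), disk)
  once <- applyClosing(holed, 1)
  expect_identical(applyClosing(once, 1), once)
})

test_that("opening strips salt noise but preserves solid regions", {
  set.seed(33)
  solid <- ellipseMask(41, 41, c(21, 21), 10, 8)
  salt <- matrix(runif(41 * 41) < 0.05, 41, 41) & !dilate4(solid)
  cleaned <- cleanMask(solid | salt, 1)
  expect_false(any(cleaned & salt))          # isolated pixels gone
  expect_true(all(cleaned[erode4(solid)]))   # interior intact
  # on the noisy phantom, cleaned evidence still rejects the atrial slice
  ph <- defaultPhantom(noiseSd = 20, seed = 1)
  img <- intensities(ph$stack)[, , , 1]
  g <- geometry(ph$stack)
  myo <- cleanMask(img >= 60 & img <= 180)
  blood <- cleanMask(img >= 260)
  expect_equal(detectBasalSlice(myo, blood, g), ph$truth@basalSlice)
})

test_that("a stroke in a uniform pool recovers the union of per-seed fills", {
  img <- matrix(50, 24, 24)
  img[5:20, 5:20] <- 300
  g <- imageGeometry(nSlices = 3, nPhases = 2)
  arr <- array(rep(img, 6), dim = c(24, 24, 3, 2))
  st <- cineStack(arr, g)
  pos <- cbind(2L, c(8L, 12L, 16L), c(8L, 12L, 16L))
  stroke <- brushStroke(pos, radius = 3, phase = 1L)
  m <- segmentStroke(st, stroke, closingRadius = 0)
  oracle <- matrix(FALSE, 24, 24)
  for (i in seq_len(nrow(pos))) {
    disk <- pixelLV:::.diskPixels(dim(img), pos[i, 2:3],
                                  pixelLV:::.diskOffsets(3))
    elig <- matrix(FALSE, 24, 24)
    elig[disk] <- TRUE
    oracle <- oracle | floodFillOracle(elig & img >= 260, pos[i, 2:3])
  }
  expect_identical(m[, , 2], oracle)
  expect_false(any(m[, , c(1, 3)]))

  # vacuous stroke, and determinism under repetition
  empty <- brushStroke(matrix(integer(), 0, 3), radius = 3)
  expect_false(any(segmentStroke(st, empty)))
  expect_identical(segmentStroke(st, stroke), segmentStroke(st, stroke))
})

test_that("enlarging fixed bounds never shrinks the pre-closing mask", {
  set.seed(21)
  g <- imageGeometry(nSlices = 3, nPhases = 2)
  arr <- array(runif(24 * 24 * 6, 0, 300), dim = c(24, 24, 3, 2))
  st <- cineStack(arr, g)
  for (rep in 1:5) {
    pos <- cbind(sample(3, 2, TRUE), sample(5:20, 2), sample(5:20, 2))
    seedInt <- arr[pos[1, 2], pos[1, 3], pos[1, 1], 1]
    lo <- seedInt - 50; hi <- seedInt + 50
    # positions may fall outside the narrow bounds: empty contribution
    narrow <- suppressWarnings(
      segmentStroke(st, brushStroke(pos, 4, 1L, c(lo, hi)),
                    closingRadius = 0))
    wide <- suppressWarnings(
      segmentStroke(st, brushStroke(pos, 4, 1L, c(lo - 60, hi + 60)),
                    closingRadius = 0))
    expect_true(all(wide[narrow]))
  }
})

test_that("on a noiseless phantom a covering stroke recovers the truth blood
           mask up to a one-pixel boundary band", {
  ph <- defaultPhantom()
  tr <- ph$truth
  truthEd <- tr@bloodMask[, , , tr@edPhase]
  m <- segmentStroke(ph$stack, bloodStroke(tr, tr@edPhase))
  disagree <- m != truthEd
  # no disagreement in the truth interior, none beyond one pixel outside
  expect_false(any(disagree & erode4(truthEd)))
  expect_false(any(disagree & !dilate4(truthEd)))
  expect_lt(sum(disagree) / sum(truthEd), 0.005)
})
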