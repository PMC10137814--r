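test_that("endocardial fill encloses papillary islands and interior holes", {
  # no papillary evidence: reduces to hole-filled blood
  blood <- ellipseMask(25, 25, c(13, 13), 8, 8)
  none <- matrix(FALSE, 25, 25)
  expect_identical(endocardialFill(blood, none), blood)

  # a blood annulus around a papillary island fills to one solid region
  island <- ellipseMask(25, 25, c(13, 13), 3, 3)
  annulus <- blood & !island
  filled <- endocardialFill(annulus, island)
  expect_identical(filled, blood)
  # even without the island marked, the enclosed hole is filled
  expect_identical(endocardialFill(annulus, none), blood)
})

test_that("on phantom slices the filled area is blood plus enclosed papillary", {
  ph <- defaultPhantom()
  tr <- ph$truth
  g <- geometry(ph$stack)
  ed <- tr@edPhase
  for (sl in 4:7) {
    b <- tr@bloodMask[, , sl, ed]
    p <- tr@papillaryMask[, , sl, ed]
    f <- endocardialFill(b, p)
    expect_equal(maskArea(f, g), maskArea(b, g) + maskArea(p, g))
  }
})

test_that("KfM minus PbM equals enclosed papillary volume, exactly on truth", {
  ph <- defaultPhantom()
  tr <- ph$truth
  g <- geometry(ph$stack)
  for (p in seq(1, geometry(ph$stack)@nPhases, by = 6)) {
    kfm <- phaseVolume(endocardialFill(tr@bloodMask[, , , p],
                                       tr@papillaryMask[, , , p]),
                       g, tr@basalSlice)
    pbm <- phaseVolume(tr@bloodMask[, , , p], g, tr@basalSlice)
    pap <- phaseVolume(tr@papillaryMask[, , , p], g, tr@basalSlice)
    expect_equal(kfm - pbm, pap)
  }
})

test_that("luminal papillary volume excludes wall-attached components", {
  g <- imageGeometry(1, 1, 10, gapFraction = 0)
  myo <- arcMask(31, 31, c(16, 16), 10, 13)

  # one wall-attached component only -> 0 mL
  attached <- ellipseMask(31, 31, c(16, 26), 2, 2) & !myo
  expect_equal(luminalPapillaryVolume(attached, myo, g), 0)

  # one free component of known pixel count
  free <- matrix(FALSE, 31, 31)
  free[15:17, 15:17] <- TRUE   # 9 px, 1 mm^2 each, 10 mm slab
  expect_equal(luminalPapillaryVolume(free, myo, g), 9 * 10 / 1000)

  # both together: only the free one counts
  expect_equal(luminalPapillaryVolume(attached | free, myo, g), 0.09)
})

test_that("phantom luminal papillary volume matches the configured fraction", {
  ph <- defaultPhantom()
  tr <- ph$truth
  g <- geometry(ph$stack)
  ed <- tr@edPhase
  lum <- luminalPapillaryVolume(tr@papillaryMask[, , , ed],
                                tr@myocardiumMask[, , , ed], g)
  expect_lt(abs(lum - tr@volumes$papillary_luminal_mL[ed]) /
              tr@volumes$papillary_luminal_mL[ed], 0.05)
  expect_lte(lum, tr@volumes$papillary_mL[ed] * 1.02)
})

test_that("including papillary muscle lowers the measured EF", {
  ph <- defaultPhantom()
  tr <- ph$truth
  g <- geometry(ph$stack)
  pbmE <- phaseVolume(tr@bloodMask[, , , tr@edPhase], g, tr@basalSlice)
  pbmS <- phaseVolume(tr@bloodMask[, , , tr@esPhase], g, tr@basalSlice)
  kfmE <- phaseVolume(endocardialFill(tr@bloodMask[, , , tr@edPhase],
                                      tr@papillaryMask[, , , tr@edPhase]),
                      g, tr@basalSlice)
  kfmS <- phaseVolume(endocardialFill(tr@bloodMask[, , , tr@esPhase],
                                      tr@papillaryMask[, , , tr@esPhase]),
                      g, tr@basalSlice)
  efPbM <- computeFunctionParams(pbmE, pbmS, "PbM")@ef
  efKfM <- computeFunctionParams(kfmE, kfmS, "KfM")@ef
  expect_gt(efPbM, efKfM)
})
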