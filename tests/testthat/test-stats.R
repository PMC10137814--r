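test_that("descriptive summaries use the sample SD convention", {
  expect_equal(describeValues(c(10, 10, 10)),
               c(mean = 10, sd = 0, min = 10, max = 10))
  d <- describeValues(c(1, 2, 3, 4))
  expect_equal(unname(d["mean"]), 2.5)
  expect_equal(unname(d["sd"]), sqrt(5 / 3), tolerance = 1e-10)  # ~1.2910
  expect_equal(unname(d[c("min", "max")]), c(1, 4))
  expect_true(is.na(describeValues(7)["sd"]))
})

test_that("percent differences match the reported cohort comparisons", {
  expect_equal(round(percentDifference(177, 188)), 6)
  expect_equal(round(percentDifference(87, 99)), 14)
  expect_equal(percentDifference(123, 123), 0)
  # relative form: percentDifference(x, x * (1 + p)) == 100 p
  for (x in c(0.5, 42, 180))
    expect_equal(percentDifference(x, x * 1.17), 17)
})

test_that("TOST declares gross non-equivalence and rejects degenerate input", {
  set.seed(4)
  a <- rnorm(30, 100, 5)
  r <- tostPaired(a, a + 50)
  expect_false(r@equivalent)
  expect_true(r@pLower > 0.99 || r@pUpper > 0.99)
  expect_error(tostPaired(a, a + 3), "zero spread")   # constant differences
  expect_error(tostPaired(a[1:2], a[1:2]), "length")
})

test_that("TOST is symmetric under swapping the two methods", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(25, 100, 8)
    b <- a + rnorm(25, runif(1, -2, 2), 3)
    r1 <- tostPaired(a, b)
    r2 <- tostPaired(b, a)
    expect_equal(r1@pLower, r2@pUpper)
    expect_equal(r1@pUpper, r2@pLower)
    expect_identical(r1@equivalent, r2@equivalent)
    expect_equal(r1@margin, r2@margin)
  }
})

test_that("a shared papillary offset leaves SV equivalent but not EF", {
  set.seed(99)
  n <- 200
  edv <- rnorm(n, 170, 35)
  esv <- pmax(20, edv * rnorm(n, 0.47, 0.05))
  pm <- rnorm(n, 14, 3)
  mk <- function(edv, esv, lab) data.frame(
    subject = seq_len(n), method = lab, edv = edv, esv = esv,
    sv = edv - esv, ef = (edv - esv) / edv)
  # the contour method sees the papillary muscle plus small measurement noise
  cohort <- rbind(mk(edv, esv, "PbM"),
                  mk(edv + pm + rnorm(n, 0, 2), esv + pm + rnorm(n, 0, 2),
                     "KfM"))
  rep <- buildCohortReport(cohort)
  sv <- rep$tost[rep$tost$parameter == "sv", ]
  ef <- rep$tost[rep$tost$parameter == "ef", ]
  expect_true(sv$equivalent)     # stroke volume unaffected by PM inclusion
  expect_false(ef$equivalent)    # EF biased downward by PM inclusion
  expect_equal(rep$reference, "PbM")

  # single-method input: descriptive columns only
  solo <- buildCohortReport(cohort[cohort$method == "PbM", ])
  expect_null(solo$tost)
  expect_equal(nrow(solo$summary), 4L)

  expect_error(buildCohortReport(cohort[0, ]), "empty")
})

test_that("subjects violating the SV consistency check are flagged", {
  n <- 10
  base <- data.frame(subject = 1:n, method = "PbM", edv = rep(160, n),
                     esv = rep(70, n), sv = rep(90, n), ef = rep(90 / 160, n))
  other <- base
  other$method <- "KfM"
  other$sv[3] <- 90 * 1.3   # 30% off
  other$edv[3] <- other$esv[3] + other$sv[3]
  other$ef <- other$sv / other$edv
  expect_warning(rep <- buildCohortReport(rbind(base, other)),
                 "re-evaluation")
  expect_equal(rep$flagged$subject, 3)
})
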