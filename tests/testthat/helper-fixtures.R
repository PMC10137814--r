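# shared fixtures and independent oracles

.fixtureCache <- new.env(parent = emptyenv())

# default-condition phantom, generated once per test run and reused
defaultPhantom <- function(noiseSd = 0, seed = 1) {
  key <- sprintf("phantom_n%g_s%d", noiseSd, seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePhantom(phantomParams(noiseSd = noiseSd),
                                            imageGeometry(), seed = seed)
  .fixtureCache[[key]]
}

# independent flood-fill oracle: grows the seed's 4-connected component by
# repeated matrix shifting until a fixed point (no queue, no shared code with
# regionGrow)
floodFillOracle <- function(eligible, seed) {
  cur <- matrix(FALSE, nrow(eligible), ncol(eligible))
  cur[seed[1L], seed[2L]] <- eligible[seed[1L], seed[2L]]
  repeat {
    grown <- cur
    grown[-1L, ] <- grown[-1L, ] | cur[-nrow(cur), ]
    grown[-nrow(cur), ] <- grown[-nrow(cur), ] | cur[-1L, ]
    grown[, -1L] <- grown[, -1L] | cur[, -ncol(cur)]
    grown[, -ncol(cur)] <- grown[, -ncol(cur)] | cur[, -1L]
    grown <- grown & eligible
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# brush strokes scripted from the truth blood mask with fixed bounds halfway
# between the blood and myocardium intensities, emulating the documented
# workflow of selecting an intensity range that captures blood
bloodStroke <- function(truth, phase, fixedLo = 260) {
  strokeFromMask(truth@bloodMask[, , , phase], radius = 4, step = 2,
                 phase = phase, fixedBounds = c(fixedLo, 1e9))
}

# a filled ellipse mask, for synthetic ring/pool fixtures
ellipseMask <- function(nr, nc, centre, rRow, rCol) {
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - centre[1L]) / rRow)^2 + ((cc - centre[2L]) / rCol)^2 <= 1
}

# 4-neighbourhood erosion/dilation by matrix shifting (2D matrix or slicewise
# 3D), independent of the package's morphology path
shift4 <- function(m, combine) {
  up <- rbind(m[-1L, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  left <- cbind(m[, -1L, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  combine(combine(combine(combine(m, up), down), left), right)
}
erode4 <- function(m) {
  if (length(dim(m)) == 3L) {
    for (s in seq_len(dim(m)[3L])) m[, , s] <- erode4(m[, , s])
    return(m)
  }
  shift4(m, `&`)
}
dilate4 <- function(m) {
  if (length(dim(m)) == 3L) {
    for (s in seq_len(dim(m)[3L])) m[, , s] <- dilate4(m[, , s])
    return(m)
  }
  shift4(m, `|`)
}

# an annular arc mask spanning [from, to] degrees around `centre`
arcMask <- function(nr, nc, centre, rInner, rOuter, from = -180, to = 180) {
  r <- matrix(seq_len(nr), nr, nc) - centre[1L]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - centre[2L]
  rad <- sqrt(r^2 + cc^2)
  ang <- atan2(cc, r) * 180 / pi
  rad >= rInner & rad <= rOuter & ang >= from & ang <= to
}
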