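#' Papillary-muscle volume from paired contour and pixel-based parameters
#'
#' If the only difference between the contour-surface (KfM) and pixel-based
#' (PbM) measurements is the enclosed papillary muscle PM, then
#' \code{ESV_KfM = ESV_PbM + PM} and \code{EDV_KfM = EDV_PbM + PM}, the two
#' stroke volumes agree, and PM can be recovered in four ways:
#' \deqn{PM_1 = EDV_{KfM} - SV_{KfM} / EF_{PbM}}
#' \deqn{PM_2 = SV_{PbM} / EF_{KfM} - EDV_{PbM}}
#' \deqn{PM_3 = EDV_{KfM} - EDV_{PbM}}
#' \deqn{PM_4 = ESV_{KfM} - ESV_{PbM}}
#' On algebraically consistent inputs all four coincide; on real measurements
#' their spread reflects measurement noise, and the mean is reported.
#'
#' @param kfm,pbm \linkS4class{FunctionParams} of the contour-surface and
#'   pixel-based measurements of the same subject.
#' @return A \linkS4class{PMEstimates}.
#' @examples
#' pbm <- computeFunctionParams(160, 70, "PbM")
#' kfm <- computeFunctionParams(175, 85, "KfM")
#' estimatePM(kfm, pbm)  # all four estimates 15 mL
#' @export
estimatePM <- function(kfm, pbm) {
  stopifnot(is(kfm, "FunctionParams"), is(pbm, "FunctionParams"))
  if (kfm@ef <= 0 || pbm@ef <= 0)
    stop("EF must be positive: the PM estimators divide by EF")
  pm1 <- kfm@edv - kfm@sv / pbm@ef
  pm2 <- pbm@sv / kfm@ef - pbm@edv
  pm3 <- kfm@edv - pbm@edv
  pm4 <- kfm@esv - pbm@esv
  new("PMEstimates", pm1 = pm1, pm2 = pm2, pm3 = pm3, pm4 = pm4,
      meanPM = mean(c(pm1, pm2, pm3, pm4)))
}

#' Aggregate papillary-muscle estimates into a formula-by-method table
#'
#' Takes one row of four estimates per method (or per subject and method) and
#' returns per-method row means, per-formula column means, and the grand
#' mean. All aggregation is done unrounded; rounding (half-even, 1 decimal)
#' happens only in the `formatted` copy of the output.
#'
#' @param estimates data.frame with a \code{method} column and numeric
#'   columns \code{pm1}..\code{pm4} (one row per method, or several rows per
#'   method which are averaged first).
#' @return A list with \code{table} (unrounded data.frame with a rowMean
#'   column), \code{columnMeans}, \code{grandMean} and \code{formatted} (the
#'   table rounded to 1 decimal for presentation).
#' @examples
#' tab <- data.frame(method = c("syngo.via", "cvi42"),
#'                   pm1 = c(13.4, 15.7), pm2 = c(15.4, 16.3),
#'                   pm3 = c(12.4, 13.9), pm4 = c(13.5, 13.3))
#' aggregatePmTable(tab)$grandMean
#' @export
aggregatePmTable <- function(estimates) {
  cols <- c("pm1", "pm2", "pm3", "pm4")
  stopifnot(is.data.frame(estimates), all(c("method", cols) %in%
                                            names(estimates)))
  if (nrow(estimates) == 0L) stop("no estimates to aggregate")
  agg <- stats::aggregate(estimates[cols],
                          by = list(method = estimates$method), FUN = mean)
  # preserve first-appearance order of methods
  agg <- agg[match(unique(estimates$method), agg$method), , drop = FALSE]
  rownames(agg) <- NULL
  agg$rowMean <- rowMeans(agg[cols])
  colMeansV <- colMeans(agg[cols])
  grand <- mean(unlist(agg[cols]))
  fmt <- agg
  fmt[c(cols, "rowMean")] <- round(fmt[c(cols, "rowMean")], 1)
  list(table = agg,
       columnMeans = colMeansV,
       grandMean = grand,
       formatted = fmt)
}
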