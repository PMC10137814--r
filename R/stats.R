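#' Descriptive summary of a vector
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum.
#' With a single value the SD is reported as NA.
#'
#' @param values numeric vector, length >= 1.
#' @return Named numeric vector \code{c(mean, sd, min, max)}.
#' @export
describeValues <- function(values) {
  stopifnot(length(values) >= 1L, !anyNA(values))
  c(mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
    min = min(values), max = max(values))
}

#' Percent difference of a mean relative to a reference
#'
#' \code{(other - reference) / reference * 100}. Presentation rounding to
#' integer percent is left to the caller ([round()] if desired).
#'
#' @param reference reference mean (> 0).
#' @param other comparison mean.
#' @return Percent difference (unrounded).
#' @examples
#' round(percentDifference(177, 188))  # 6
#' round(percentDifference(87, 99))    # 14
#' @export
percentDifference <- function(reference, other) {
  stopifnot(reference > 0)
  (other - reference) / reference * 100
}

#' Paired TOST equivalence test with a Cohen's d margin
#'
#' Two one-sided paired t-tests of the hypotheses that the mean paired
#' difference lies beyond an equivalence margin, against the alternative that
#' it lies within. The margin is expressed as a Cohen's d multiple of the
#' standard deviation of the paired differences (the d_z convention), the
#' only margin computable from paired data alone. Equivalence is declared
#' when both one-sided p-values are below `alpha`.
#'
#' @param a,b subject-aligned numeric vectors (same parameter, two methods).
#' @param d Cohen's d defining the margin (default 0.3).
#' @param alpha significance level (default 0.05).
#' @return A \linkS4class{TOSTResult}. Differences are taken as \code{a - b};
#'   the verdict is symmetric in the two arguments.
#' @export
tostPaired <- function(a, b, d = 0.3, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 3L,
            !anyNA(a), !anyNA(b), d > 0, alpha > 0, alpha < 1)
  diffs <- a - b
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0)
    stop("the paired differences have zero spread; the Cohen's d margin is ",
         "degenerate (identical methods or a data error)")
  margin <- d * s
  se <- s / sqrt(n)
  df <- n - 1L
  # H0 lower: mean <= -margin, rejected for large (m + margin)/se
  pLower <- stats::pt((m + margin) / se, df, lower.tail = FALSE)
  # H0 upper: mean >= +margin, rejected for small (m - margin)/se
  pUpper <- stats::pt((m - margin) / se, df, lower.tail = TRUE)
  new("TOSTResult",
      meanDiff = m, sdDiff = s, margin = margin,
      pLower = pLower, pUpper = pUpper,
      equivalent = pLower < alpha && pUpper < alpha,
      alpha = alpha, cohensD = m / s, n = as.integer(n))
}

#' Cohort report: per-method summaries plus equivalence tests
#'
#' Builds the per-parameter, per-method grid of means and SDs and runs paired
#' TOST equivalence tests of SV and EF for every method against a reference
#' method. Subjects whose SV differs from the reference by more than
#' `svCheckPct` percent are flagged for re-evaluation (the quality-control
#' rule of the pixel-based workflow).
#'
#' @param cohort data.frame with columns \code{subject}, \code{method},
#'   \code{edv}, \code{esv}, \code{sv}, \code{ef} (volumes mL, EF a
#'   fraction).
#' @param reference method label used as the comparison reference; defaults
#'   to \code{"PbM"} if present, else the first method.
#' @param d,alpha TOST margin (Cohen's d) and significance level.
#' @param svCheckPct per-subject SV discrepancy (percent) above which a
#'   subject is flagged.
#' @return A list of class \code{cohortReport}: \code{summary} (parameter x
#'   method means/SDs), \code{tost} (data.frame of TOST results for SV and
#'   EF per comparison), \code{flagged} (data.frame of subject/method pairs
#'   exceeding the SV check), \code{reference}.
#' @export
buildCohortReport <- function(cohort, reference = NULL, d = 0.3,
                              alpha = 0.05, svCheckPct = 15) {
  need <- c("subject", "method", "edv", "esv", "sv", "ef")
  stopifnot(is.data.frame(cohort), all(need %in% names(cohort)))
  if (nrow(cohort) == 0L) stop("empty cohort table")
  methods <- unique(cohort$method)
  if (is.null(reference))
    reference <- if ("PbM" %in% methods) "PbM" else methods[1L]
  stopifnot(reference %in% methods)

  params <- c("edv", "esv", "sv", "ef")
  summ <- do.call(rbind, lapply(params, function(p) {
    row <- data.frame(parameter = p)
    for (m in methods) {
      v <- cohort[[p]][cohort$method == m]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sd")]] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    }
    row
  }))

  tost <- NULL
  flagged <- NULL
  others <- setdiff(methods, reference)
  if (length(others) > 0L) {
    ref <- cohort[cohort$method == reference, ]
    for (m in others) {
      oth <- cohort[cohort$method == m, ]
      common <- intersect(ref$subject, oth$subject)
      if (length(common) < 3L) next
      refI <- match(common, ref$subject)
      othI <- match(common, oth$subject)
      for (p in c("sv", "ef")) {
        tr <- tostPaired(ref[[p]][refI], oth[[p]][othI], d = d, alpha = alpha)
        tost <- rbind(tost, data.frame(
          parameter = p, reference = reference, method = m, n = tr@n,
          mean_diff = tr@meanDiff, margin = tr@margin,
          p_lower = tr@pLower, p_upper = tr@pUpper,
          equivalent = tr@equivalent))
      }
      svDiffPct <- abs(oth$sv[othI] - ref$sv[refI]) / ref$sv[refI] * 100
      bad <- svDiffPct > svCheckPct
      if (any(bad)) {
        flagged <- rbind(flagged, data.frame(
          subject = common[bad], method = m, sv_diff_pct = svDiffPct[bad]))
        warning(sum(bad), " subject(s) differ in SV by more than ",
                svCheckPct, "% between ", reference, " and ", m,
                "; re-evaluation recommended")
      }
    }
  }
  structure(list(summary = summ, tost = tost,
                 flagged = flagged, reference = reference),
            class = "cohortReport")
}

#' @export
print.cohortReport <- function(x, ...) {
  cat("Cohort report (reference method:", x$reference, ")\n\n")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, 2)
  print(s, row.names = FALSE)
  if (!is.null(x$tost)) {
    cat("\nPaired TOST equivalence (Cohen's d margin):\n")
    t <- x$tost
    t$mean_diff <- round(t$mean_diff, 3)
    t$margin <- round(t$margin, 3)
    t$p_lower <- signif(t$p_lower, 3)
    t$p_upper <- signif(t$p_upper, 3)
    print(t, row.names = FALSE)
  }
  if (!is.null(x$flagged))
    cat("\n", nrow(x$flagged), "subject(s) flagged by the SV check\n")
  invisible(x)
}
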