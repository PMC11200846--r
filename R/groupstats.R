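# Cross-subject inference on decoding curves: exact one-sided Wilcoxon
# signed-rank tests against chance, per-timepoint significance masks, and
# modality-difference curves. With 6 subjects the large-sample Wilcoxon
# approximation is invalid, so the exact null distribution is used.

#' Exact one-sided Wilcoxon signed-rank p-value
#'
#' Computes the exact tail probability of the positive rank sum under the
#' sign-flip null. Zero differences are dropped before ranking (standard
#' signed-rank convention) and ties are mid-ranked. For n <= 25 the exact
#' null distribution over all \eqn{2^n} sign assignments is evaluated by a
#' generating-function convolution over the (doubled, hence integer)
#' ranks, which is identical to full enumeration; above n = 25 a
#' continuity-corrected normal approximation with tie-corrected variance
#' is used.
#'
#' @param diffs per-subject differences.
#' @param alternative "greater" (right tail) or "less".
#' @return the p-value; all-zero input gives 1 with a warning.
#' @examples
#' wilcoxonSignedRankExact(c(3, 1, 4, 1, 5, 9))  # all positive: 1/64
#' @export
wilcoxonSignedRankExact <- function(diffs, alternative = c("greater",
                                                           "less")) {
  alternative <- match.arg(alternative)
  d <- diffs[diffs != 0]
  if (length(d) == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))  # mid-ranks doubled are integers
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (v in r2)
      counts <- counts + c(rep(0, v), counts[seq_len(total + 1L - v)])
    W2 <- as.integer(round(2 * W))
    p <- if (alternative == "greater")
      sum(counts[(W2 + 1L):(total + 1L)]) / 2^n
    else
      sum(counts[seq_len(W2 + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(sum(r^2) / 4)
    p <- if (alternative == "greater")
      stats::pnorm((W - 0.5 - mu) / sig, lower.tail = FALSE)
    else
      stats::pnorm((W + 0.5 - mu) / sig)
  }
  min(1, p)
}

.curveMatrix <- function(curves) {
  times <- epochTimes(curves[[1L]])
  for (c in curves[-1L]) {
    if (length(epochTimes(c)) != length(times) ||
        max(abs(epochTimes(c) - times)) > 1e-9)
      stop("curves do not share a time grid")
  }
  list(times = times,
       acc = do.call(rbind, lapply(curves, accuracy)))
}

#' Group-level significance of decoding curves against chance
#'
#' Per timepoint, tests the per-subject accuracies against the chance
#' level with the exact one-sided (greater) Wilcoxon signed-rank test. No
#' correction is applied across timepoints: per-timepoint discs are
#' reported as-is, and false-discovery control is reserved for channel
#' selection — interpret long runs of isolated significant points with
#' care.
#'
#' @param curves list of [AccuracyCurve-class] objects on one time grid.
#' @param chance chance accuracy (0.5 for balanced binary labels).
#' @param alpha significance level.
#' @return a [GroupResult-class].
#' @export
groupSignificance <- function(curves, chance = 0.5, alpha = 0.05) {
  cm <- .curveMatrix(curves)
  p <- vapply(seq_along(cm$times), function(t)
    suppressWarnings(wilcoxonSignedRankExact(cm$acc[, t] - chance,
                                             "greater")),
    numeric(1L))
  new("GroupResult", times = cm$times, meanAccuracy = colMeans(cm$acc),
      pValues = p, significant = p <= alpha, alpha = alpha,
      nSubjects = length(curves), alternative = "greater")
}

#' Test per-subject curve differences against zero
#'
#' Forms subject-matched difference curves (a minus b) and applies the
#' exact one-sided Wilcoxon test against zero at each timepoint.
#'
#' @param curvesA,curvesB subject-matched lists of [AccuracyCurve-class]
#'   objects on one time grid.
#' @param alpha significance level.
#' @return a [GroupResult-class] whose \code{meanAccuracy} slot holds the
#'   mean difference curve.
#' @export
differenceCurves <- function(curvesA, curvesB, alpha = 0.05) {
  idsA <- vapply(curvesA, subjectId, character(1L))
  idsB <- vapply(curvesB, subjectId, character(1L))
  if (!setequal(idsA, idsB) || anyDuplicated(idsA))
    stop("subject sets differ between the two curve lists")
  curvesB <- curvesB[match(idsA, idsB)]
  a <- .curveMatrix(curvesA)
  b <- .curveMatrix(curvesB)
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("curves do not share a time grid")
  D <- a$acc - b$acc
  p <- vapply(seq_along(a$times), function(t)
    suppressWarnings(wilcoxonSignedRankExact(D[, t], "greater")),
    numeric(1L))
  new("GroupResult", times = a$times, meanAccuracy = colMeans(D),
      pValues = p, significant = p <= alpha, alpha = alpha,
      nSubjects = length(curvesA), alternative = "greater")
}
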