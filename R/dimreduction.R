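# Spatial feature reduction: train-fitted standardization,
# variance-threshold PCA, and univariate channel selection by paired
# permutation t-test with Benjamini-Hochberg control.

#' Construct a ReducerSpec
#'
#' @param method "none", "pca" (variance-threshold PCA fitted fold-wise on
#'   training data) or "univariate" (channel selection by permutation
#'   t-test over a time window, BH-corrected).
#' @param pcaVarThreshold fraction of training variance PCA must retain.
#' @param selectWindow scored time window (s) for channel selection.
#' @param nPermutations permutation count (values below 100 warn).
#' @param alpha per-test level used by the parametric fallback.
#' @param bhQ Benjamini-Hochberg false-discovery level.
#' @param paired pair trials by stimulus id (sign-flip null) when possible.
#' @param parametric use the paired-t reference distribution instead of the
#'   permutation null.
#' @param seed permutation seed.
#' @return a validated [ReducerSpec-class].
#' @export
ReducerSpec <- function(method = c("pca", "none", "univariate"),
                        pcaVarThreshold = 0.99,
                        selectWindow = c(0.2, 0.6),
                        nPermutations = 1000L, alpha = 0.05, bhQ = 0.05,
                        paired = TRUE, parametric = FALSE, seed = 1L) {
  new("ReducerSpec", method = match.arg(method),
      pcaVarThreshold = as.numeric(pcaVarThreshold),
      selectWindow = as.numeric(selectWindow),
      nPermutations = as.integer(nPermutations), alpha = as.numeric(alpha),
      bhQ = as.numeric(bhQ), paired = isTRUE(paired),
      parametric = isTRUE(parametric), seed = as.integer(seed))
}

#' Fit a per-feature standardizer on training rows
#'
#' Estimates per-feature mean and SD on training rows only. Zero-SD
#' (constant) features are flagged; [applyStandardizer()] maps them to 0.
#'
#' @param trainMatrix trials x features numeric matrix (>= 2 rows).
#' @return list with \code{mean}, \code{sd} and \code{zeroSd} (logical).
#' @export
fitStandardizer <- function(trainMatrix) {
  if (nrow(trainMatrix) < 2L)
    stop("at least 2 training rows are required")
  mu <- colMeans(trainMatrix)
  n <- nrow(trainMatrix)
  sdv <- sqrt(pmax(0, colMeans(trainMatrix^2) - mu^2) * n / (n - 1L))
  zero <- sdv == 0
  if (any(zero))
    warning(sum(zero), " zero-variance feature(s) will be mapped to 0")
  sdv[zero] <- 1
  list(mean = mu, sd = sdv, zeroSd = zero)
}

#' Apply a fitted standardizer
#'
#' @param params a fit from [fitStandardizer()].
#' @param matrix rows x features matrix with the training feature count.
#' @return the standardized matrix; zero-SD training features become 0.
#' @export
applyStandardizer <- function(params, matrix) {
  if (ncol(matrix) != length(params$mean))
    stop("feature count does not match the fitted standardizer")
  out <- sweep(sweep(matrix, 2L, params$mean), 2L, params$sd, "/")
  if (any(params$zeroSd)) out[, params$zeroSd] <- 0
  out
}

#' Variance-threshold PCA fitted on training rows only
#'
#' Chooses the smallest number of leading principal components whose
#' cumulative explained variance on the training data reaches
#' \code{varThreshold}, then projects both matrices onto them. Test rows
#' never influence the fitted projection.
#'
#' @param trainMatrix standardized training matrix (trials x features).
#' @param testMatrix standardized matrix to co-project (may be NULL).
#' @param varThreshold variance fraction in (0, 1].
#' @return list with \code{train}, \code{test}, \code{nComponents} and the
#'   projection matrix \code{rotation}.
#' @export
pcaReduce <- function(trainMatrix, testMatrix = NULL, varThreshold = 0.99) {
  if (varThreshold <= 0 || varThreshold > 1)
    stop("varThreshold must lie in (0, 1]")
  if (nrow(trainMatrix) < 2L)
    stop("at least 2 training rows are required")
  mu <- colMeans(trainMatrix)
  Xc <- sweep(trainMatrix, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  ev <- ev[seq_len(rank)]
  cumvar <- cumsum(ev) / sum(ev)
  m <- which(cumvar >= varThreshold - 1e-12)[1L]
  rot <- sv$v[, seq_len(m), drop = FALSE]
  project <- function(M) sweep(M, 2L, mu) %*% rot
  list(train = project(trainMatrix),
       test = if (is.null(testMatrix)) NULL else project(testMatrix),
       nComponents = m, rotation = rot)
}

#' Benjamini-Hochberg step-up selection mask
#'
#' Returns the rejection mask of the BH step-up rule at false-discovery
#' level \code{q}: with sorted p-values, find the largest i with
#' p_(i) <= (i/m) q and reject all hypotheses at or below it.
#'
#' @param pValues p-values in \eqn{[0, 1]}.
#' @param q false-discovery level.
#' @return logical mask of rejected hypotheses (empty input, empty mask).
#' @export
bhAdjust <- function(pValues, q = 0.05) {
  if (length(pValues) == 0L) return(logical(0))
  if (any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH") <= q
}

#' Univariate channel selection by permutation t-test
#'
#' Scores each channel by the t-statistic of the condition difference of
#' per-trial mean amplitude over \code{selectWindow}, paired across
#' stimulus ids when available. The permutation null is built by
#' within-pair sign flipping (unpaired fallback: label shuffling), the
#' two-sided permutation p-value uses the add-one rule
#' \eqn{(1 + \#\{|t_{perm}| \ge |t_{obs}|\})/(1 + n_{perm})}, and the
#' Benjamini-Hochberg step-up rule at \code{bhQ} is applied across
#' channels. An empty selection is returned as an all-FALSE mask with a
#' warning; callers decide the fallback.
#'
#' @param E an [EpochsSet-class].
#' @param spec a [ReducerSpec-class].
#' @return logical channel mask with attributes \code{"tObs"} and
#'   \code{"pValues"}.
#' @export
univariateSelectChannels <- function(E, spec) {
  win <- spec@selectWindow
  idx <- which(E@times >= win[1L] - 1e-12 & E@times <= win[2L] + 1e-12)
  if (length(idx) == 0L)
    stop("selectWindow contains no samples")
  if (spec@nPermutations < 100L && !spec@parametric)
    warning("fewer than 100 permutations gives a coarse p-value grid")
  # trials x channels matrix of window-mean amplitude
  M <- rowMeans(E@data[, , idx, drop = FALSE], dims = 2L)
  paired <- spec@paired && !anyNA(E@pairIds) &&
    length(intersect(E@pairIds[E@labels == 0L],
                     E@pairIds[E@labels == 1L])) >= 2L
  set.seed(spec@seed)
  if (paired) {
    common <- intersect(E@pairIds[E@labels == 0L],
                        E@pairIds[E@labels == 1L])
    i0 <- match(common, ifelse(E@labels == 0L, E@pairIds, NA))
    i1 <- match(common, ifelse(E@labels == 1L, E@pairIds, NA))
    D <- M[i1, , drop = FALSE] - M[i0, , drop = FALSE]  # pairs x channels
    n <- nrow(D)
    S2 <- colSums(D^2)
    # sum(d^2) is sign-flip invariant, so t follows from the flipped mean
    tFromMean <- function(m) {
      v <- if (is.matrix(m)) sweep(-(n * m^2), 2L, S2, "+") / (n - 1L)
           else (S2 - n * m^2) / (n - 1L)
      m / sqrt(pmax(v, 0) / n)
    }
    tObs <- tFromMean(colMeans(D))
    if (spec@parametric) {
      p <- 2 * pt(abs(tObs), df = n - 1L, lower.tail = FALSE)
    } else {
      signs <- matrix(sample(c(-1, 1), spec@nPermutations * n,
                             replace = TRUE),
                      spec@nPermutations, n)
      Mperm <- signs %*% D / n  # permutation means, perms x channels
      exceed <- colSums(abs(tFromMean(Mperm)) >=
                        rep(abs(tObs), each = spec@nPermutations))
      p <- (1 + exceed) / (1 + spec@nPermutations)
    }
  } else {
    y <- E@labels
    tStat <- function(lab) {
      m1 <- colMeans(M[lab == 1L, , drop = FALSE])
      m0 <- colMeans(M[lab == 0L, , drop = FALSE])
      v1 <- apply(M[lab == 1L, , drop = FALSE], 2L, var)
      v0 <- apply(M[lab == 0L, , drop = FALSE], 2L, var)
      (m1 - m0) / sqrt(v1 / sum(lab == 1L) + v0 / sum(lab == 0L))
    }
    tObs <- tStat(y)
    if (spec@parametric) {
      p <- 2 * pt(abs(tObs), df = length(y) - 2L, lower.tail = FALSE)
    } else {
      exceed <- numeric(length(tObs))
      for (b in seq_len(spec@nPermutations)) {
        tp <- tStat(y[sample.int(length(y))])
        exceed <- exceed + (abs(tp) >= abs(tObs))
      }
      p <- (1 + exceed) / (1 + spec@nPermutations)
    }
  }
  mask <- bhAdjust(p, spec@bhQ)
  if (!any(mask))
    warning("no channel survives BH selection; caller decides the fallback")
  attr(mask, "tObs") <- tObs
  attr(mask, "pValues") <- p
  mask
}
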