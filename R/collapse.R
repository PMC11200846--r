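# Epoch-conditioning and SNR-collapse operators. Every operator preserves
# the channel axis and label alphabet; only the trial and/or time axes
# change.

#' Construct a CollapseConfig
#'
#' @param resampleHz target rate (Hz) for anti-alias resampling, or NA.
#' @param windowLenMs sliding-window length (ms), or NA for none.
#' @param windowStepFraction step size as a fraction of the window length.
#' @param avgGroupSize trials averaged per pseudo-trial (1 = single-trial).
#' @param baselineInterval baseline-correction interval (s).
#' @param zscoreThreshold epoch-rejection threshold on max |z|, or NA.
#' @param seed seed for the stochastic steps.
#' @return a validated [CollapseConfig-class].
#' @export
CollapseConfig <- function(resampleHz = NA_real_, windowLenMs = NA_real_,
                           windowStepFraction = 0.6, avgGroupSize = 1L,
                           baselineInterval = c(-0.2, 0),
                           zscoreThreshold = NA_real_, seed = 1L) {
  new("CollapseConfig", resampleHz = as.numeric(resampleHz),
      windowLenMs = as.numeric(windowLenMs),
      windowStepFraction = as.numeric(windowStepFraction),
      avgGroupSize = as.integer(avgGroupSize),
      baselineInterval = as.numeric(baselineInterval),
      zscoreThreshold = as.numeric(zscoreThreshold), seed = as.integer(seed))
}

.replaceTrials <- function(E, data, labels, pairIds) {
  new("EpochsSet", data = data, labels = as.integer(labels),
      pairIds = as.integer(pairIds), times = E@times, sfreq = E@sfreq,
      channelIds = E@channelIds, modality = E@modality,
      subjectId = E@subjectId)
}

.replaceTimes <- function(E, data, times, sfreq) {
  new("EpochsSet", data = data, labels = E@labels, pairIds = E@pairIds,
      times = as.numeric(times), sfreq = as.numeric(sfreq),
      channelIds = E@channelIds, modality = E@modality,
      subjectId = E@subjectId)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval.
#' Idempotent; after correction the mean over the interval is zero.
#'
#' @param E an [EpochsSet-class].
#' @param interval numeric length-2, interval in seconds (inclusive).
#' @return the corrected [EpochsSet-class].
#' @export
baselineCorrect <- function(E, interval = c(-0.2, 0)) {
  idx <- which(E@times >= interval[1L] - 1e-12 &
               E@times <= interval[2L] + 1e-12)
  if (length(idx) == 0L)
    stop("baseline interval contains no samples")
  means <- rowMeans(E@data[, , idx, drop = FALSE], dims = 2L)
  data <- E@data - as.vector(means)  # recycles over the timepoint axis
  .replaceTimes(E, data, E@times, E@sfreq)
}

#' Flag and drop bad epochs by z-score
#'
#' Standardizes each channel across all trials and timepoints, summarizes
#' each trial by its maximum absolute z over channels and timepoints, and
#' drops trials exceeding the threshold. Pairing metadata of survivors is
#' preserved.
#'
#' @param E an [EpochsSet-class].
#' @param threshold positive rejection threshold on max |z|.
#' @return list with \code{kept} ([EpochsSet-class]) and \code{rejected}
#'   (integer trial indices).
#' @export
flagBadEpochs <- function(E, threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be a positive number")
  if (threshold <= 0) stop("threshold must be positive")
  d <- dim(E@data)
  # per-channel mean/sd across trials and timepoints
  chMat <- matrix(aperm(E@data, c(1L, 3L, 2L)), ncol = d[2L])
  mu <- colMeans(chMat)
  sdv <- sqrt(colMeans(chMat^2) - mu^2) * sqrt(nrow(chMat) /
                                               (nrow(chMat) - 1L))
  sdv[sdv == 0] <- 1
  z <- abs(sweep(sweep(chMat, 2L, mu), 2L, sdv, "/"))
  # rows of chMat are (trial, time) with trial varying fastest
  trialIdx <- rep_len(seq_len(d[1L]), nrow(chMat))
  rowMax <- do.call(pmax, lapply(seq_len(ncol(z)), function(j) z[, j]))
  summary <- unname(vapply(split(rowMax, trialIdx), max, numeric(1L)))
  rejected <- which(summary > threshold)
  if (length(rejected) == d[1L])
    stop("all trials exceed the z-score threshold; raise the threshold")
  keep <- setdiff(seq_len(d[1L]), rejected)
  list(kept = .replaceTrials(E, E@data[keep, , , drop = FALSE],
                             E@labels[keep], E@pairIds[keep]),
       rejected = rejected)
}

# Zero-phase frequency-domain low-pass: unit gain up to `pass` Hz,
# raised-cosine roll-off to zero at `stop` Hz. Operates columnwise on a
# timepoints x series matrix.
.fftLowpass <- function(mat, sfreq, pass, stop) {
  nT <- nrow(mat)
  freqs <- (seq_len(nT) - 1L) / nT * sfreq
  freqs <- pmin(freqs, sfreq - freqs)  # two-sided spectrum
  gain <- rep(1, nT)
  trans <- freqs > pass & freqs < stop
  gain[trans] <- 0.5 * (1 + cos(pi * (freqs[trans] - pass) / (stop - pass)))
  gain[freqs >= stop] <- 0
  Re(mvfft(mvfft(mat) * gain, inverse = TRUE)) / nT
}

#' Resample epochs with anti-alias filtering
#'
#' Applies a zero-phase low-pass (raised-cosine transition from 0.8 to 1.0
#' times the new Nyquist frequency) and decimates by the integer factor
#' \code{sfreq / targetHz}. Zero-phase filtering preserves component
#' latencies. \code{targetHz == sfreq} is an identity.
#'
#' @param E an [EpochsSet-class].
#' @param targetHz target sampling rate; must divide the native rate.
#' @return the resampled [EpochsSet-class].
#' @export
resampleEpochs <- function(E, targetHz) {
  if (!is.finite(targetHz) || targetHz <= 0)
    stop("targetHz must be positive")
  if (targetHz > E@sfreq)
    stop("targetHz must not exceed the native sampling rate")
  if (abs(targetHz - E@sfreq) < 1e-9) return(E)
  factor <- E@sfreq / targetHz
  if (abs(factor - round(factor)) > 1e-9)
    stop("only integer decimation factors are supported")
  factor <- round(factor)
  d <- dim(E@data)
  nyq <- targetHz / 2
  mat <- matrix(aperm(E@data, c(3L, 1L, 2L)), nrow = d[3L])
  filtered <- .fftLowpass(mat, E@sfreq, pass = 0.8 * nyq, stop = nyq)
  keep <- seq(1L, d[3L], by = factor)
  dec <- filtered[keep, , drop = FALSE]
  data <- aperm(array(dec, dim = c(length(keep), d[1L], d[2L])),
                c(2L, 3L, 1L))
  .replaceTimes(E, data, E@times[keep], targetHz)
}

#' Sliding-window average over time
#'
#' Averages samples inside windows of \code{windowLenMs} milliseconds
#' anchored at the epoch start, advancing by
#' \code{round(stepFraction * L)} samples; only windows wholly inside the
#' epoch are kept. Output timestamps are the window centers.
#'
#' @param E an [EpochsSet-class].
#' @param windowLenMs window length in milliseconds.
#' @param stepFraction step size as a fraction of the window length.
#' @return the time-collapsed [EpochsSet-class].
#' @export
slidingWindowAverage <- function(E, windowLenMs, stepFraction = 0.6) {
  L <- round(windowLenMs / 1000 * E@sfreq)
  if (L < 1L) stop("window shorter than one sample at the current rate")
  nT <- dim(E@data)[3L]
  if (L > nT) stop("window longer than the epoch")
  if (stepFraction <= 0 || stepFraction > 1)
    stop("stepFraction must lie in (0, 1]")
  step <- max(1L, round(stepFraction * L))
  starts <- seq(1L, nT - L + 1L, by = step)
  d <- dim(E@data)
  out <- array(0, dim = c(d[1L], d[2L], length(starts)))
  for (w in seq_along(starts)) {
    sel <- starts[w]:(starts[w] + L - 1L)
    out[, , w] <- rowMeans(E@data[, , sel, drop = FALSE], dims = 2L)
  }
  centers <- E@times[starts] + (L - 1L) / (2 * E@sfreq)
  .replaceTimes(E, out, centers, E@sfreq / step)
}

#' Average trials into pseudo-trials
#'
#' Within each condition, trials are randomly partitioned (seeded) into
#' disjoint groups of exactly \code{groupSize}; each group is averaged into
#' one pseudo-trial. Leftover trials are dropped so pseudo-trial noise
#' variance stays homogeneous. Pair ids are invalidated (set to NA).
#'
#' @param E an [EpochsSet-class].
#' @param groupSize trials per pseudo-trial; 1 is the identity (ordering
#'   aside).
#' @param seed partition seed.
#' @param returnGroups also return the trial grouping used.
#' @return the pseudo-trial [EpochsSet-class] (with attribute
#'   \code{"groups"} when \code{returnGroups}), labels inherited.
#' @export
averageTrials <- function(E, groupSize, seed = 1L, returnGroups = FALSE) {
  groupSize <- as.integer(groupSize)
  if (groupSize < 1L) stop("groupSize must be >= 1")
  counts <- table(factor(E@labels, levels = c(0L, 1L)))
  if (any(counts < groupSize))
    stop("fewer trials than groupSize in at least one condition")
  set.seed(seed)
  pieces <- list()
  labsOut <- integer(0)
  groups <- list()
  for (lab in c(0L, 1L)) {
    idx <- which(E@labels == lab)
    idx <- idx[sample.int(length(idx))]
    nGroups <- length(idx) %/% groupSize
    idx <- idx[seq_len(nGroups * groupSize)]
    grp <- matrix(idx, nrow = groupSize)
    for (g in seq_len(nGroups)) {
      sel <- grp[, g]
      avg <- colMeans(array(E@data[sel, , , drop = FALSE],
                            dim = c(groupSize, dim(E@data)[2L],
                                    dim(E@data)[3L])))
      pieces[[length(pieces) + 1L]] <- avg
      groups[[length(groups) + 1L]] <- sel
      labsOut <- c(labsOut, lab)
    }
  }
  d <- dim(E@data)
  data <- array(0, dim = c(length(pieces), d[2L], d[3L]))
  for (i in seq_along(pieces)) data[i, , ] <- pieces[[i]]
  out <- .replaceTrials(E, data, labsOut, rep(NA_integer_, length(labsOut)))
  if (returnGroups) attr(out, "groups") <- groups
  out
}

#' Balance class counts by downsampling
#'
#' Randomly (seeded) downsamples the majority class to the minority count.
#' Already-balanced input is returned with its trial set unchanged.
#'
#' @param E an [EpochsSet-class].
#' @param seed downsampling seed.
#' @return the balanced [EpochsSet-class].
#' @export
balanceEpochs <- function(E, seed = 1L) {
  n0 <- sum(E@labels == 0L)
  n1 <- sum(E@labels == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present")
  if (n0 == n1) return(E)
  set.seed(seed)
  minority <- min(n0, n1)
  majLab <- if (n0 > n1) 0L else 1L
  majIdx <- which(E@labels == majLab)
  keepMaj <- sort(majIdx[sample.int(length(majIdx), minority)])
  keep <- sort(c(which(E@labels != majLab), keepMaj))
  E[keep]
}

#' Apply the time-axis collapse steps of a config
#'
#' Runs baseline correction, optional z-score flagging, optional
#' resampling and optional sliding-window averaging, in that order.
#' Trial-axis steps (balancing, pseudo-trial averaging) are applied by
#' [decodeTimecourse()] in the documented order
#' balance -> collapse-time -> average-trials.
#'
#' @param E an [EpochsSet-class].
#' @param config a [CollapseConfig-class].
#' @return the conditioned [EpochsSet-class].
#' @export
collapseTime <- function(E, config) {
  E <- baselineCorrect(E, config@baselineInterval)
  if (!is.na(config@zscoreThreshold))
    E <- flagBadEpochs(E, config@zscoreThreshold)$kept
  if (!is.na(config@resampleHz))
    E <- resampleEpochs(E, config@resampleHz)
  if (!is.na(config@windowLenMs))
    E <- slidingWindowAverage(E, config@windowLenMs,
                              config@windowStepFraction)
  E
}
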