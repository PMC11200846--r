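# Synthetic evoked-data generator.
#
# The generator emulates a paired two-condition auditory paradigm: each of
# nTrials/2 stimuli appears once per condition (pair ids), the incongruent
# condition carries an extra smooth component peaking near 400 ms on a
# subset of channels, both conditions share earlier stimulus-locked
# components, and the noise is temporally AR(1)-colored, spatially
# correlated across a 1-d channel ordering, with additive white sensor
# noise. Random streams are split per (seed, subject, role) so that adding
# subjects to a cohort never perturbs earlier subjects' data.

#' Construct a SimulationSpec
#'
#' Defaults describe the emulated study: 6 subjects, 196 trials split over
#' two conditions with stimulus pairing, 40 magnetometer-scale and 64
#' electrode-scale channels, epochs from -200 ms to 1000 ms at 1000 Hz,
#' and a condition-difference component peaking at 400 ms.
#'
#' @param nSubjects cohort size.
#' @param nTrials trials per subject (even).
#' @param nChannelsMeg,nChannelsEeg channels per modality.
#' @param sfreq sampling frequency, Hz.
#' @param epochWindow numeric length-2, epoch window (s), tMin < 0 < tMax.
#' @param effectLatency condition-difference peak time, s.
#' @param effectWidth full width of the Hanning taper, s.
#' @param effectAmplitude effect peak amplitude in units of the background
#'   noise SD; 0 gives a null model with labels independent of the data.
#' @param effectChannelFraction fraction of channels carrying the effect.
#' @param sharedComponents matrix with columns (latency, width, amplitude)
#'   of components common to both conditions.
#' @param ar1Coefficient lag-1 autocorrelation of the background noise.
#' @param spatialCorrelationLength squared-exponential kernel length
#'   (channels) of the spatial noise correlation.
#' @param backgroundNoiseSd marginal SD of the colored background noise.
#' @param sensorNoiseSd white sensor-noise SD.
#' @param amplitudeSd between-subject SD of the effect amplitude scale.
#' @param latencyJitterSd between-subject SD of the effect latency, s.
#' @param megScale,eegScale physical scale factors (tesla- and volt-like).
#' @param seed base seed.
#' @return a validated [SimulationSpec-class].
#' @examples
#' spec <- SimulationSpec(nSubjects = 2, nTrials = 8, nChannelsMeg = 4,
#'                        nChannelsEeg = 6, sfreq = 100)
#' spec
#' @export
SimulationSpec <- function(nSubjects = 6L,
                           nTrials = 196L,
                           nChannelsMeg = 40L,
                           nChannelsEeg = 64L,
                           sfreq = 1000,
                           epochWindow = c(-0.2, 1.0),
                           effectLatency = 0.40,
                           effectWidth = 0.15,
                           effectAmplitude = 0.12,
                           effectChannelFraction = 0.5,
                           sharedComponents = rbind(c(0.10, 0.10, 1.5),
                                                    c(0.20, 0.14, 1.0)),
                           ar1Coefficient = 0.95,
                           spatialCorrelationLength = 5,
                           backgroundNoiseSd = 1,
                           sensorNoiseSd = 0.3,
                           amplitudeSd = 0.2,
                           latencyJitterSd = 0.02,
                           megScale = 1e-13,
                           eegScale = 1e-6,
                           seed = 1L) {
  sharedComponents <- matrix(as.numeric(sharedComponents), ncol = 3L,
                             dimnames = list(NULL,
                                             c("latency", "width",
                                               "amplitude")))
  new("SimulationSpec",
      nSubjects = as.integer(nSubjects), nTrials = as.integer(nTrials),
      nChannelsMeg = as.integer(nChannelsMeg),
      nChannelsEeg = as.integer(nChannelsEeg),
      sfreq = as.numeric(sfreq),
      tMin = as.numeric(epochWindow[1L]), tMax = as.numeric(epochWindow[2L]),
      effectLatency = as.numeric(effectLatency),
      effectWidth = as.numeric(effectWidth),
      effectAmplitude = as.numeric(effectAmplitude),
      effectChannelFraction = as.numeric(effectChannelFraction),
      sharedComponents = sharedComponents,
      ar1Coefficient = as.numeric(ar1Coefficient),
      spatialCorrelationLength = as.numeric(spatialCorrelationLength),
      backgroundNoiseSd = as.numeric(backgroundNoiseSd),
      sensorNoiseSd = as.numeric(sensorNoiseSd),
      amplitudeSd = as.numeric(amplitudeSd),
      latencyJitterSd = as.numeric(latencyJitterSd),
      megScale = as.numeric(megScale), eegScale = as.numeric(eegScale),
      seed = as.integer(seed))
}

# Deterministic stream seeds: fold integers into [0, 2^31 - 2] without
# exceeding double precision (multiplier kept small on purpose).
.deriveSeed <- function(...) {
  vals <- c(...)
  h <- 17
  for (v in vals) h <- (h * 69621 + (as.numeric(v) %% 69621) + 1) %% 2147483562
  as.integer(h)
}

# Hanning-tapered bump: peak 1 at center, support [center - w/2, center + w/2].
.hanningBump <- function(times, center, width) {
  u <- (times - center) / width
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# Random spatial pattern over a channel subset, normalized to max |w| = 1.
.spatialPattern <- function(nChannels, fraction, streamSeed) {
  set.seed(streamSeed)
  nCarry <- ceiling(fraction * nChannels)
  idx <- sort(sample.int(nChannels, nCarry))
  w <- numeric(nChannels)
  w[idx] <- rnorm(nCarry)
  w / max(abs(w))
}

# Colored, spatially correlated noise for one (trials x channels x times)
# block. Marginal SD of the AR(1) component is `bgSd` (stationary
# initialization, so variance is constant over the epoch); white sensor
# noise is added on top.
.generateNoise <- function(nTrials, nChannels, nTimes, phi, ell, bgSd,
                           sensorSd, streamSeed) {
  set.seed(streamSeed)
  out <- array(0, dim = c(nTrials, nChannels, nTimes))
  if (bgSd > 0) {
    # rows of z index (time, trial) with time fastest; columns = channels
    z <- matrix(rnorm(nTimes * nTrials * nChannels),
                nTimes * nTrials, nChannels)
    if (ell > 0 && nChannels > 1L) {
      idx <- seq_len(nChannels)
      K <- exp(-outer(idx, idx, "-")^2 / (2 * ell^2))
      diag(K) <- diag(K) + 1e-8
      z <- z %*% chol(K)
    }
    m <- matrix(z, nTimes, nTrials * nChannels)
    if (phi > 0) {
      # innovation variance 1 - phi^2 keeps the marginal variance at 1;
      # the first sample keeps full variance (stationary start)
      m[-1L, ] <- m[-1L, ] * sqrt(1 - phi^2)
      m <- matrix(stats::filter(m, phi, method = "recursive"), nTimes)
    }
    out <- aperm(array(bgSd * m, dim = c(nTimes, nTrials, nChannels)),
                 c(2L, 3L, 1L))
  }
  if (sensorSd > 0)
    out <- out + array(sensorSd * rnorm(nTrials * nChannels * nTimes),
                       dim = c(nTrials, nChannels, nTimes))
  out
}

# Subject-level draw of effect amplitude scale and latency.
.subjectParams <- function(spec, subjectIndex) {
  set.seed(.deriveSeed(spec@seed, subjectIndex, 101L))
  ampScale <- max(0, 1 + spec@amplitudeSd * rnorm(1L))
  latency <- spec@effectLatency + spec@latencyJitterSd * rnorm(1L)
  list(ampScale = ampScale, latency = latency)
}

# Paired trial layout shared by both modalities of one subject: each pair
# id appears once per condition, in a seeded pseudo-random order.
.trialLayout <- function(spec, subjectIndex) {
  set.seed(.deriveSeed(spec@seed, subjectIndex, 102L))
  nPairs <- spec@nTrials %/% 2L
  labels <- rep(c(0L, 1L), each = nPairs)
  pairs <- rep(seq_len(nPairs), times = 2L)
  ord <- sample.int(spec@nTrials)
  list(labels = labels[ord], pairIds = pairs[ord])
}

.buildModality <- function(spec, subjectIndex, modality, layout, subj,
                           times) {
  nChannels <- if (modality == "meg") spec@nChannelsMeg else spec@nChannelsEeg
  scale <- if (modality == "meg") spec@megScale else spec@eegScale
  modCode <- if (modality == "meg") 1L else 2L
  nT <- length(times)

  # Spatial patterns are fixed properties of the simulated "head": they
  # depend on the base seed and modality, not on the subject.
  effectW <- .spatialPattern(nChannels, spec@effectChannelFraction,
                             .deriveSeed(spec@seed, modCode, 201L))
  shared <- matrix(0, nChannels, nT)
  if (nrow(spec@sharedComponents) > 0) {
    for (k in seq_len(nrow(spec@sharedComponents))) {
      w <- .spatialPattern(nChannels, 1,
                           .deriveSeed(spec@seed, modCode, 300L + k))
      comp <- spec@sharedComponents[k, ]
      shared <- shared + comp[["amplitude"]] *
        outer(w, .hanningBump(times, comp[["latency"]], comp[["width"]]))
    }
  }
  effect <- subj$ampScale * spec@effectAmplitude *
    outer(effectW, .hanningBump(times, subj$latency, spec@effectWidth))

  noise <- .generateNoise(spec@nTrials, nChannels, nT,
                          spec@ar1Coefficient,
                          spec@spatialCorrelationLength,
                          spec@backgroundNoiseSd, spec@sensorNoiseSd,
                          .deriveSeed(spec@seed, subjectIndex,
                                      400L + modCode))

  data <- noise
  base <- shared
  withEffect <- shared + effect
  for (i in seq_len(spec@nTrials)) {
    sig <- if (layout$labels[i] == 1L) withEffect else base
    data[i, , ] <- data[i, , ] + sig
  }
  data <- data * scale

  EpochsSet(data, labels = layout$labels, pairIds = layout$pairIds,
            times = times, sfreq = spec@sfreq, modality = modality,
            subjectId = sprintf("sub-%02d", subjectIndex))
}

#' Generate one subject's dual-modality epochs
#'
#' Returns magnetometer- and electrode-scale epoch sets with identical
#' labels, pair ids and time grid. The condition difference is a smooth
#' Hanning bump at the (subject-jittered) effect latency projected onto a
#' fixed random spatial pattern; both conditions share the earlier
#' stimulus-locked components. Output is deterministic given
#' \code{(spec@seed, subjectIndex)}.
#'
#' @param spec a [SimulationSpec-class].
#' @param subjectIndex 1-based subject index.
#' @param modalities which modalities to build; each modality has its own
#'   random stream, so generating only \code{"meg"} reproduces the meg
#'   element of a dual-modality run bit-identically.
#' @return a list with elements \code{meg} and/or \code{eeg},
#'   [EpochsSet-class] objects.
#' @examples
#' spec <- SimulationSpec(nTrials = 8, nChannelsMeg = 4, nChannelsEeg = 6,
#'                        sfreq = 50)
#' s <- generateSubject(spec, 1)
#' s$meg
#' @export
generateSubject <- function(spec, subjectIndex,
                            modalities = c("meg", "eeg")) {
  validObject(spec)
  modalities <- match.arg(modalities, several.ok = TRUE)
  subjectIndex <- as.integer(subjectIndex)
  if (subjectIndex < 1L)
    stop("subjectIndex must be >= 1")
  nT <- round((spec@tMax - spec@tMin) * spec@sfreq)
  times <- spec@tMin + (seq_len(nT) - 1L) / spec@sfreq
  layout <- .trialLayout(spec, subjectIndex)
  subj <- .subjectParams(spec, subjectIndex)
  out <- lapply(setNames(modalities, modalities), function(m)
    .buildModality(spec, subjectIndex, m, layout, subj, times))
  out
}

#' Generate a cohort of subjects
#'
#' Per-subject effect amplitude scales and latency jitters are drawn from
#' the between-subject variability model; every subject's data depend only
#' on \code{(seed, subjectIndex)}, so extending the cohort reproduces the
#' earlier subjects bit-identically.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed optional override of \code{spec@seed}.
#' @param modalities which modalities to build per subject.
#' @return a list of length \code{nSubjects}; each element a list with
#'   \code{meg} and/or \code{eeg} [EpochsSet-class] objects.
#' @export
generateCohort <- function(spec, seed = NULL,
                           modalities = c("meg", "eeg")) {
  validObject(spec)
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  lapply(seq_len(spec@nSubjects),
         function(i) generateSubject(spec, i, modalities = modalities))
}

#' Noise-free evoked responses implied by a SimulationSpec
#'
#' Evaluates the generative signal model (shared components plus the
#' condition-difference bump) on the epoch grid for one subject, without
#' noise. Used to validate peak recovery against the generative equation.
#'
#' @param spec a [SimulationSpec-class].
#' @param subjectIndex 1-based subject index.
#' @param modality "meg" or "eeg".
#' @return list with \code{times}, \code{congruent} and \code{incongruent}
#'   channels x timepoints matrices (in physical units).
#' @export
evokedTemplates <- function(spec, subjectIndex = 1L, modality = "meg") {
  validObject(spec)
  noiseless <- spec
  noiseless@backgroundNoiseSd <- 0
  noiseless@sensorNoiseSd <- 0
  noiseless@nTrials <- 2L
  s <- generateSubject(noiseless, subjectIndex)[[modality]]
  d <- epochsData(s)
  i0 <- which(trialLabels(s) == 0L)[1L]
  i1 <- which(trialLabels(s) == 1L)[1L]
  list(times = epochTimes(s),
       congruent = d[i0, , , drop = TRUE],
       incongruent = d[i1, , , drop = TRUE])
}
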