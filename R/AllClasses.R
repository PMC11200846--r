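#' @import methods
#' @importFrom stats rnorm runif sd var predict quantile pt p.adjust cor
#'   t.test dnorm qnorm fft mvfft setNames aggregate
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC dens sim nMclustParams cdens
#'   cdensV cdensVVI cdensVVV simV simVVI simVVV
NULL

.MODALITIES <- c("meg", "eeg", "fused")

#' Container for epoched multichannel evoked recordings
#'
#' An \code{EpochsSet} holds a trials x channels x timepoints array of
#' evoked responses together with the metadata every analysis stage needs:
#' a binary condition label per trial (0 = congruent, 1 = incongruent), a
#' pairing identifier linking the two conditions of one stimulus (sentence
#' body), the time axis in seconds, the sampling frequency, channel names,
#' the recording modality and a subject identifier.
#'
#' @slot data numeric array, trials x channels x timepoints, in physical
#'   units (tesla-scale for magnetometers, volt-scale for electrodes).
#' @slot labels integer vector of 0/1 condition codes, one per trial.
#' @slot pairIds integer vector linking paired trials; \code{NA} marks
#'   trials whose pairing is no longer meaningful (e.g. pseudo-trials).
#' @slot times numeric vector of timepoints in seconds, uniformly spaced.
#' @slot sfreq sampling frequency in Hz.
#' @slot channelIds character vector of channel names.
#' @slot modality one of \code{"meg"}, \code{"eeg"}, \code{"fused"}.
#' @slot subjectId subject identifier string.
#'
#' @seealso [EpochsSet()] for the user-facing constructor,
#'   [generateSubject()] to simulate one.
#' @exportClass EpochsSet
setClass("EpochsSet",
  slots = c(
    data = "array",
    labels = "integer",
    pairIds = "integer",
    times = "numeric",
    sfreq = "numeric",
    channelIds = "character",
    modality = "character",
    subjectId = "character"
  )
)

setValidity("EpochsSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array (trials x channels x timepoints)")
  if (length(object@labels) != d[1L])
    return("length(labels) must equal the number of trials")
  if (length(object@pairIds) != d[1L])
    return("length(pairIds) must equal the number of trials")
  if (length(object@channelIds) != d[2L])
    return("length(channelIds) must equal the number of channels")
  if (length(object@times) != d[3L])
    return("length(times) must equal the number of timepoints")
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must take values in {0, 1}")
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    return("sfreq must be a single positive number")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      return("times must be strictly increasing")
    if (any(abs(dt - 1 / object@sfreq) > 1e-9))
      return("times spacing must equal 1/sfreq (tolerance 1e-9 s)")
  }
  for (lab in c(0L, 1L)) {
    ids <- object@pairIds[object@labels == lab]
    ids <- ids[!is.na(ids)]
    if (anyDuplicated(ids))
      return("each pair id may occur at most once per label value")
  }
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    return(sprintf("modality must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  if (length(object@subjectId) != 1L)
    return("subjectId must be a single string")
  TRUE
})

#' Generative parameters for synthetic evoked cohorts
#'
#' A \code{SimulationSpec} fully describes a simulated study: cohort size,
#' trial and channel counts, epoch timing, the condition-difference
#' component (a smooth Hanning bump, by default peaking at 400 ms to mimic
#' an N400m-like semantic-congruity effect), stimulus-locked components
#' shared by both conditions, the noise model (temporally AR(1)-colored,
#' spatially correlated, plus white sensor noise) and between-subject
#' variability. Setting \code{effectAmplitude = 0} yields a null model in
#' which labels and data are independent by construction.
#'
#' @slot nSubjects number of subjects in a cohort.
#' @slot nTrials trials per subject (even; half per condition).
#' @slot nChannelsMeg,nChannelsEeg channels per modality.
#' @slot sfreq sampling frequency, Hz.
#' @slot tMin,tMax epoch window bounds in seconds (tMin < 0 < tMax).
#' @slot effectLatency peak time of the condition difference, s.
#' @slot effectWidth full width of the Hanning taper carrying the effect, s.
#' @slot effectAmplitude effect size in units of noise SD; 0 = null model.
#' @slot effectChannelFraction fraction of channels carrying the effect.
#' @slot sharedComponents matrix with columns latency, width, amplitude of
#'   bumps common to both conditions.
#' @slot ar1Coefficient lag-1 autocorrelation of the colored noise.
#' @slot spatialCorrelationLength squared-exponential kernel length over the
#'   1-d channel ordering, in channels.
#' @slot backgroundNoiseSd marginal SD of the colored background noise;
#'   this is the unit in which \code{effectAmplitude} is expressed.
#' @slot sensorNoiseSd white sensor-noise SD (same units).
#' @slot amplitudeSd,latencyJitterSd between-subject SDs of the effect
#'   amplitude scale (unitless) and latency (s).
#' @slot megScale,eegScale physical scale factors applied to the two
#'   modalities (tesla-like and volt-like).
#' @slot seed base seed for all random streams.
#'
#' @seealso [SimulationSpec()], [generateSubject()], [generateCohort()]
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  slots = c(
    nSubjects = "integer",
    nTrials = "integer",
    nChannelsMeg = "integer",
    nChannelsEeg = "integer",
    sfreq = "numeric",
    tMin = "numeric",
    tMax = "numeric",
    effectLatency = "numeric",
    effectWidth = "numeric",
    effectAmplitude = "numeric",
    effectChannelFraction = "numeric",
    sharedComponents = "matrix",
    ar1Coefficient = "numeric",
    spatialCorrelationLength = "numeric",
    backgroundNoiseSd = "numeric",
    sensorNoiseSd = "numeric",
    amplitudeSd = "numeric",
    latencyJitterSd = "numeric",
    megScale = "numeric",
    eegScale = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  chk1 <- function(x, nm, pos = FALSE, nonneg = FALSE) {
    if (length(x) != 1L || !is.finite(x))
      return(sprintf("%s must be a single finite value", nm))
    if (pos && x <= 0) return(sprintf("%s must be > 0", nm))
    if (nonneg && x < 0) return(sprintf("%s must be >= 0", nm))
    NULL
  }
  for (nm in c("nSubjects", "nTrials", "nChannelsMeg", "nChannelsEeg",
               "sfreq", "effectWidth", "megScale", "eegScale"))
    if (!is.null(m <- chk1(slot(object, nm), nm, pos = TRUE))) return(m)
  for (nm in c("effectAmplitude", "ar1Coefficient", "backgroundNoiseSd",
               "sensorNoiseSd", "amplitudeSd", "latencyJitterSd",
               "spatialCorrelationLength"))
    if (!is.null(m <- chk1(slot(object, nm), nm, nonneg = TRUE))) return(m)
  if (object@nTrials %% 2L != 0L)
    return("nTrials must be even (paired two-condition design)")
  if (object@effectChannelFraction <= 0 || object@effectChannelFraction > 1)
    return("effectChannelFraction must lie in (0, 1]")
  if (!(object@tMin < 0 && 0 < object@tMax))
    return("epoch window must satisfy tMin < 0 < tMax")
  if (object@ar1Coefficient >= 1)
    return("ar1Coefficient must be < 1 (stationarity)")
  if (ncol(object@sharedComponents) != 3L)
    return("sharedComponents must have columns (latency, width, amplitude)")
  TRUE
})

#' SNR-collapse configuration
#'
#' Describes the epoch-conditioning stage of one pipeline variant:
#' baseline correction interval, optional z-score epoch flagging, optional
#' anti-alias resampling, optional sliding-window averaging and
#' pseudo-trial (within-condition) averaging. Unused steps are \code{NA}.
#'
#' @slot resampleHz target sampling rate in Hz or \code{NA} for none.
#' @slot windowLenMs sliding-window length in ms or \code{NA} for none.
#' @slot windowStepFraction window step as a fraction of the length.
#' @slot avgGroupSize trials averaged per pseudo-trial (1 = single-trial).
#' @slot baselineInterval two-element numeric, baseline interval in s.
#' @slot zscoreThreshold epoch-rejection threshold on max |z|, or \code{NA}.
#' @slot seed seed for the stochastic steps (grouping, balancing).
#' @exportClass CollapseConfig
setClass("CollapseConfig",
  slots = c(
    resampleHz = "numeric",
    windowLenMs = "numeric",
    windowStepFraction = "numeric",
    avgGroupSize = "integer",
    baselineInterval = "numeric",
    zscoreThreshold = "numeric",
    seed = "integer"
  )
)

setValidity("CollapseConfig", function(object) {
  if (object@windowStepFraction <= 0 || object@windowStepFraction > 1)
    return("windowStepFraction must lie in (0, 1]")
  if (object@avgGroupSize < 1L)
    return("avgGroupSize must be >= 1")
  if (length(object@baselineInterval) != 2L)
    return("baselineInterval must have two elements")
  if (!is.na(object@zscoreThreshold) && object@zscoreThreshold <= 0)
    return("zscoreThreshold must be positive")
  TRUE
})

#' Dimensionality-reduction configuration
#'
#' @slot method one of \code{"none"}, \code{"pca"}, \code{"univariate"}.
#' @slot pcaVarThreshold fraction of variance PCA must retain.
#' @slot selectWindow time window (s) scored by the channel selector.
#' @slot nPermutations permutation count for the channel test.
#' @slot alpha per-test level (parametric fallback).
#' @slot bhQ Benjamini-Hochberg false-discovery level.
#' @slot paired use within-pair sign flipping when pair ids are available.
#' @slot parametric use the paired t distribution instead of permutation.
#' @slot seed permutation seed.
#' @exportClass ReducerSpec
setClass("ReducerSpec",
  slots = c(
    method = "character",
    pcaVarThreshold = "numeric",
    selectWindow = "numeric",
    nPermutations = "integer",
    alpha = "numeric",
    bhQ = "numeric",
    paired = "logical",
    parametric = "logical",
    seed = "integer"
  )
)

setValidity("ReducerSpec", function(object) {
  if (!(object@method %in% c("none", "pca", "univariate")))
    return("method must be one of none, pca, univariate")
  if (object@pcaVarThreshold <= 0 || object@pcaVarThreshold > 1)
    return("pcaVarThreshold must lie in (0, 1]")
  if (length(object@selectWindow) != 2L ||
      object@selectWindow[1L] >= object@selectWindow[2L])
    return("selectWindow must be an increasing two-element window")
  TRUE
})

#' Classifier configuration
#'
#' The three decoders mirror common linear/nonlinear choices for evoked
#' decoding: LDA (svd solver, no shrinkage, tolerance 1e-4), ridge
#' regression used as a classifier (alpha = 1, targets -1/+1, sign
#' threshold) and an SVM with sigmoid kernel (tolerance 1e-4, shrinking).
#'
#' @slot kind one of \code{"lda"}, \code{"ridge"}, \code{"svm_sigmoid"}.
#' @slot tolerance numerical tolerance passed to the solver.
#' @slot ridgeAlpha ridge regularization strength.
#' @slot svmGamma sigmoid-kernel coefficient; \code{NA} means
#'   \code{1 / (n_features * var(features))}.
#' @slot svmCoef0 sigmoid-kernel offset.
#' @slot svmShrinking use shrinking heuristics in the SVM solver.
#' @slot seed seed (only the SVM solver is order-sensitive).
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  slots = c(
    kind = "character",
    tolerance = "numeric",
    ridgeAlpha = "numeric",
    svmGamma = "numeric",
    svmCoef0 = "numeric",
    svmShrinking = "logical",
    seed = "integer"
  )
)

setValidity("ClassifierSpec", function(object) {
  if (!(object@kind %in% c("lda", "ridge", "svm_sigmoid")))
    return("kind must be one of lda, ridge, svm_sigmoid")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@ridgeAlpha <= 0) return("ridgeAlpha must be > 0")
  TRUE
})

#' Complete description of one decoding variant
#'
#' Bundles the collapse, reduction, classifier and cross-validation choices
#' plus the master seed; two runs with equal configs are reproducible.
#'
#' @slot collapse a [CollapseConfig-class].
#' @slot reducer a [ReducerSpec-class].
#' @slot classifier a [ClassifierSpec-class].
#' @slot cvFolds stratified fold count (>= 2).
#' @slot chanceLevel chance accuracy (0.5 for balanced binary labels).
#' @slot seed master seed; stage seeds derive from it.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(
    collapse = "CollapseConfig",
    reducer = "ReducerSpec",
    classifier = "ClassifierSpec",
    cvFolds = "integer",
    chanceLevel = "numeric",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@cvFolds < 2L) return("cvFolds must be >= 2")
  if (object@chanceLevel <= 0 || object@chanceLevel >= 1)
    return("chanceLevel must lie in (0, 1)")
  TRUE
})

#' Per-subject time-resolved decoding accuracy
#'
#' @slot subjectId subject identifier.
#' @slot times timepoints (s) of the decoded grid.
#' @slot accuracy fold-mean accuracy per timepoint.
#' @slot perFold folds x timepoints accuracy matrix.
#' @slot configId readable identifier of the generating [PipelineConfig-class].
#' @exportClass AccuracyCurve
setClass("AccuracyCurve",
  slots = c(
    subjectId = "character",
    times = "numeric",
    accuracy = "numeric",
    perFold = "matrix",
    configId = "character"
  )
)

setValidity("AccuracyCurve", function(object) {
  if (length(object@accuracy) != length(object@times))
    return("accuracy and times must have equal length")
  if (ncol(object@perFold) != length(object@times))
    return("perFold must have one column per timepoint")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    return("accuracy must lie in [0, 1]")
  if (max(abs(colMeans(object@perFold) - object@accuracy)) > 1e-12)
    return("accuracy must equal the fold mean (tolerance 1e-12)")
  TRUE
})

#' Group-level inference on decoding curves
#'
#' @slot times timepoints (s).
#' @slot meanAccuracy cross-subject mean accuracy (or mean difference).
#' @slot pValues per-timepoint one-sided Wilcoxon p-values.
#' @slot significant logical mask, \code{pValues <= alpha}.
#' @slot alpha significance level.
#' @slot nSubjects number of subjects tested.
#' @slot alternative test direction (\code{"greater"}).
#' @exportClass GroupResult
setClass("GroupResult",
  slots = c(
    times = "numeric",
    meanAccuracy = "numeric",
    pValues = "numeric",
    significant = "logical",
    alpha = "numeric",
    nSubjects = "integer",
    alternative = "character"
  )
)

setValidity("GroupResult", function(object) {
  n <- length(object@times)
  if (length(object@meanAccuracy) != n || length(object@pValues) != n ||
      length(object@significant) != n)
    return("times, meanAccuracy, pValues, significant must share length")
  if (any(object@pValues < 0 | object@pValues > 1))
    return("pValues must lie in [0, 1]")
  if (!identical(object@significant, object@pValues <= object@alpha))
    return("significant mask must equal pValues <= alpha")
  TRUE
})

#' Paired benchmark/reduced observation sets
#'
#' Rows of \code{benchmark} and \code{operated} refer one-to-one to the
#' same underlying observation (a trial x timepoint sample); \code{operated}
#' holds the representation a reduction operation assigns to it.
#'
#' @slot benchmark observations x d_x matrix (full channel vectors).
#' @slot operated observations x d_y matrix (reduced representations).
#' @slot dimension which data dimension was reduced: \code{"channel"},
#'   \code{"trial"} or \code{"temporal"}.
#' @slot mapping human-readable description of the operation.
#' @slot subjectId subject identifier.
#' @exportClass ReductionPair
setClass("ReductionPair",
  slots = c(
    benchmark = "matrix",
    operated = "matrix",
    dimension = "character",
    mapping = "character",
    subjectId = "character"
  )
)

setValidity("ReductionPair", function(object) {
  if (nrow(object@benchmark) != nrow(object@operated))
    return("benchmark and operated must have equal observation counts")
  if (!(object@dimension %in% c("channel", "trial", "temporal")))
    return("dimension must be one of channel, trial, temporal")
  TRUE
})

#' Mutual-information estimate with fitting metadata
#'
#' @slot miPerRepeat per-repeat KSG estimates, nats.
#' @slot miMean repeat-averaged estimate, clipped at 0, nats.
#' @slot miDensityPerRepeat density-ratio diagnostic per repeat, nats.
#' @slot nComponentsX,nComponentsY,nComponentsJoint AIC-selected mixture
#'   component counts.
#' @slot nMcSamples Monte-Carlo sample count per repeat.
#' @slot kNn neighbour count of the KSG estimator.
#' @slot seed seed used.
#' @exportClass MIResult
setClass("MIResult",
  slots = c(
    miPerRepeat = "numeric",
    miMean = "numeric",
    miDensityPerRepeat = "numeric",
    nComponentsX = "integer",
    nComponentsY = "integer",
    nComponentsJoint = "integer",
    nMcSamples = "integer",
    kNn = "integer",
    seed = "integer"
  )
)

setValidity("MIResult", function(object) {
  if (object@miMean < 0) return("miMean is clipped at 0 from below")
  if (abs(object@miMean - max(0, mean(object@miPerRepeat))) > 1e-12)
    return("miMean must be the clipped mean of miPerRepeat")
  TRUE
})

#' Pearson correlation result
#'
#' @slot r correlation coefficient.
#' @slot p two-sided p-value from the t distribution with n - 2 df.
#' @slot n number of points.
#' @slot xLabel,yLabel variable names.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(
    r = "numeric",
    p = "numeric",
    n = "integer",
    xLabel = "character",
    yLabel = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r must lie in [-1, 1]")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})
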