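#' Construct an EpochsSet
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param labels integer-like 0/1 condition labels, one per trial.
#' @param pairIds integer-like pairing ids (NA where pairing is void).
#' @param times timepoints in seconds, or NULL to build them from
#'   \code{tMin} and \code{sfreq}.
#' @param sfreq sampling frequency, Hz.
#' @param channelIds channel names; autogenerated when NULL.
#' @param modality one of "meg", "eeg", "fused".
#' @param subjectId subject identifier.
#' @param tMin epoch start (s), used when \code{times} is NULL.
#' @return a validated [EpochsSet-class].
#' @examples
#' e <- EpochsSet(array(rnorm(4 * 3 * 10), c(4, 3, 10)),
#'                labels = c(0, 1, 0, 1), pairIds = c(1, 1, 2, 2),
#'                sfreq = 100, tMin = -0.02, modality = "meg",
#'                subjectId = "s01")
#' nTrials(e)
#' @export
EpochsSet <- function(data, labels, pairIds = rep(NA_integer_, dim(data)[1L]),
                      times = NULL, sfreq, channelIds = NULL,
                      modality = "meg", subjectId = "unknown", tMin = NULL) {
  if (is.null(times)) {
    if (is.null(tMin))
      stop("either 'times' or 'tMin' must be given")
    times <- tMin + (seq_len(dim(data)[3L]) - 1L) / sfreq
  }
  if (is.null(channelIds))
    channelIds <- sprintf("%s%03d", toupper(modality), seq_len(dim(data)[2L]))
  new("EpochsSet", data = data, labels = as.integer(labels),
      pairIds = as.integer(pairIds), times = as.numeric(times),
      sfreq = as.numeric(sfreq), channelIds = as.character(channelIds),
      modality = modality, subjectId = subjectId)
}

#' Accessors for EpochsSet
#'
#' @param x an [EpochsSet-class].
#' @return the corresponding slot value; \code{nTrials}, \code{nChannels}
#'   and \code{nTimepoints} return the array extents.
#' @name EpochsSet-accessors
NULL

#' @rdname EpochsSet-accessors
#' @export
setMethod("epochsData", "EpochsSet", function(x) x@data)

#' @rdname EpochsSet-accessors
#' @export
setMethod("trialLabels", "EpochsSet", function(x) x@labels)

#' @rdname EpochsSet-accessors
#' @export
setMethod("pairIds", "EpochsSet", function(x) x@pairIds)

#' @rdname EpochsSet-accessors
#' @export
setMethod("epochTimes", "EpochsSet", function(x) x@times)

#' @rdname EpochsSet-accessors
#' @export
setMethod("samplingRate", "EpochsSet", function(x) x@sfreq)

#' @rdname EpochsSet-accessors
#' @export
setMethod("channelIds", "EpochsSet", function(x) x@channelIds)

#' @rdname EpochsSet-accessors
#' @export
setMethod("modality", "EpochsSet", function(x) x@modality)

#' @rdname EpochsSet-accessors
#' @export
setMethod("subjectId", "EpochsSet", function(x) x@subjectId)

#' @rdname EpochsSet-accessors
#' @export
setMethod("nTrials", "EpochsSet", function(x) dim(x@data)[1L])

#' @rdname EpochsSet-accessors
#' @export
setMethod("nChannels", "EpochsSet", function(x) dim(x@data)[2L])

#' @rdname EpochsSet-accessors
#' @export
setMethod("nTimepoints", "EpochsSet", function(x) dim(x@data)[3L])

#' Subset an EpochsSet by trial
#'
#' \code{x[i]} keeps trials \code{i} (data, labels and pair ids together).
#'
#' @param x an [EpochsSet-class].
#' @param i trial indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an [EpochsSet-class] with the selected trials.
#' @export
setMethod("[", "EpochsSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochsSet", data = x@data[i, , , drop = FALSE],
      labels = x@labels[i], pairIds = x@pairIds[i], times = x@times,
      sfreq = x@sfreq, channelIds = x@channelIds, modality = x@modality,
      subjectId = x@subjectId)
})

setMethod("show", "EpochsSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochsSet '%s' (%s): %d trials x %d channels x %d timepoints\n",
              object@subjectId, object@modality, d[1L], d[2L], d[3L]))
  cat(sprintf("  window %.3f..%.3f s at %g Hz; labels: %d/%d (0/1)\n",
              object@times[1L], object@times[length(object@times)],
              object@sfreq, sum(object@labels == 0L),
              sum(object@labels == 1L)))
  invisible(NULL)
})

#' Accessors for AccuracyCurve
#'
#' @param x an [AccuracyCurve-class].
#' @name AccuracyCurve-accessors
NULL

#' @rdname AccuracyCurve-accessors
#' @export
setMethod("accuracy", "AccuracyCurve", function(x) x@accuracy)

#' @rdname AccuracyCurve-accessors
#' @export
setMethod("perFold", "AccuracyCurve", function(x) x@perFold)

#' @rdname AccuracyCurve-accessors
#' @export
setMethod("epochTimes", "AccuracyCurve", function(x) x@times)

#' @rdname AccuracyCurve-accessors
#' @export
setMethod("subjectId", "AccuracyCurve", function(x) x@subjectId)

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve '%s': %d timepoints, %d folds, peak %.3f at %d ms\n",
              object@subjectId, length(object@times), nrow(object@perFold),
              max(object@accuracy),
              round(1000 * object@times[which.max(object@accuracy)])))
  invisible(NULL)
})

#' Accessors for GroupResult
#'
#' @param x a [GroupResult-class].
#' @name GroupResult-accessors
NULL

#' @rdname GroupResult-accessors
#' @export
setMethod("pValues", "GroupResult", function(x) x@pValues)

#' @rdname GroupResult-accessors
#' @export
setMethod("significantMask", "GroupResult", function(x) x@significant)

#' @rdname GroupResult-accessors
#' @export
setMethod("meanAccuracy", "GroupResult", function(x) x@meanAccuracy)

#' @rdname GroupResult-accessors
#' @export
setMethod("epochTimes", "GroupResult", function(x) x@times)

setMethod("show", "GroupResult", function(object) {
  cat(sprintf(paste0("GroupResult: %d subjects, %d timepoints, %d significant",
                     " at alpha = %g (%s)\n"),
              object@nSubjects, length(object@times),
              sum(object@significant), object@alpha, object@alternative))
  invisible(NULL)
})

#' Accessors for MIResult
#'
#' @param x an [MIResult-class].
#' @name MIResult-accessors
NULL

#' @rdname MIResult-accessors
#' @export
setMethod("miMean", "MIResult", function(x) x@miMean)

#' @rdname MIResult-accessors
#' @export
setMethod("miPerRepeat", "MIResult", function(x) x@miPerRepeat)

setMethod("show", "MIResult", function(object) {
  cat(sprintf(paste0("MIResult: %.4f nats (mean of %d repeats, %d MC samples,",
                     " k = %d)\n  mixture components x/y/joint: %d/%d/%d\n"),
              object@miMean, length(object@miPerRepeat), object@nMcSamples,
              object@kNn, object@nComponentsX, object@nComponentsY,
              object@nComponentsJoint))
  invisible(NULL)
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: r = %.3f, p = %.4g, n = %d (%s vs %s)\n",
              object@r, object@p, object@n, object@xLabel, object@yLabel))
  invisible(NULL)
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d subjects x %d trials, %d meg + %d eeg",
                     " channels, %g Hz, window %.2f..%.2f s\n",
                     "  effect: amp %.3g at %.0f ms (width %.0f ms) on %.0f%%",
                     " of channels; seed %d\n"),
              object@nSubjects, object@nTrials, object@nChannelsMeg,
              object@nChannelsEeg, object@sfreq, object@tMin, object@tMax,
              object@effectAmplitude, 1000 * object@effectLatency,
              1000 * object@effectWidth, 100 * object@effectChannelFraction,
              object@seed))
  invisible(NULL)
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:", configId(object), "\n")
  invisible(NULL)
})

#' Readable identifier of a pipeline configuration
#'
#' A compact string spelling out every parameter that affects results;
#' equal strings imply reproducibly equal pipelines (given equal inputs).
#'
#' @param config a [PipelineConfig-class].
#' @return a single string.
#' @export
configId <- function(config) {
  cl <- config@collapse
  rd <- config@reducer
  cf <- config@classifier
  fmt <- function(x) if (is.na(x)) "none" else format(x)
  paste0(
    "collapse[bl=", cl@baselineInterval[1L], ":", cl@baselineInterval[2L],
    ",rs=", fmt(cl@resampleHz), ",win=", fmt(cl@windowLenMs),
    "x", cl@windowStepFraction, ",avg=", cl@avgGroupSize,
    ",z=", fmt(cl@zscoreThreshold), "]",
    "|reducer[", rd@method, ",var=", rd@pcaVarThreshold,
    ",win=", rd@selectWindow[1L], ":", rd@selectWindow[2L],
    ",q=", rd@bhQ, "]",
    "|clf[", cf@kind, ",tol=", cf@tolerance, ",alpha=", cf@ridgeAlpha, "]",
    "|cv=", config@cvFolds, "|chance=", config@chanceLevel,
    "|seed=", config@seed)
}
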