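#' @rdname EpochsSet-accessors
#' @export
setGeneric("epochsData", function(x) standardGeneric("epochsData"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EpochsSet-accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname AccuracyCurve-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname AccuracyCurve-accessors
#' @export
setGeneric("perFold", function(x) standardGeneric("perFold"))

#' @rdname GroupResult-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname GroupResult-accessors
#' @export
setGeneric("significantMask", function(x) standardGeneric("significantMask"))

#' @rdname GroupResult-accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname MIResult-accessors
#' @export
setGeneric("miMean", function(x) standardGeneric("miMean"))

#' @rdname MIResult-accessors
#' @export
setGeneric("miPerRepeat", function(x) standardGeneric("miPerRepeat"))
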