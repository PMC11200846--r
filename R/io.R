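# On-disk interchange. Epochs are stored as a pair of files sharing a
# stem: `<stem>.json` holds all metadata (shape, labels, pair ids, times,
# sampling rate, channel names, modality, subject) and `<stem>.bin` holds
# the raw little-endian float64 array in column-major (Fortran) order of
# (trials, channels, timepoints). The layout is self-describing and
# readable from Python via
#   numpy.fromfile(stem + ".bin").reshape(shape, order="F").

#' Write an EpochsSet to disk
#'
#' @param E an [EpochsSet-class].
#' @param stem path without extension; \code{<stem>.json} and
#'   \code{<stem>.bin} are written.
#' @return the stem, invisibly.
#' @export
writeEpochs <- function(E, stem) {
  validObject(E)
  meta <- list(
    format = "evoked-epochs-raw",
    version = 1L,
    shape = dim(E@data),
    order = "F",
    dtype = "float64",
    byteorder = "little",
    labels = E@labels,
    pair_ids = E@pairIds,
    times = E@times,
    sfreq = E@sfreq,
    channel_ids = E@channelIds,
    modality = E@modality,
    subject_id = E@subjectId)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(E@data), con, size = 8L, endian = "little")
  invisible(stem)
}

#' Read an EpochsSet from disk
#'
#' Reads the layout written by [writeEpochs()]; the round trip is
#' bit-exact. Missing metadata fields or a truncated data file raise
#' errors naming the problem rather than returning a partial object.
#'
#' @param stem path without extension.
#' @return an [EpochsSet-class].
#' @export
readEpochs <- function(stem) {
  jsonPath <- paste0(stem, ".json")
  binPath <- paste0(stem, ".bin")
  if (!file.exists(jsonPath)) stop("metadata file not found: ", jsonPath)
  if (!file.exists(binPath)) stop("data file not found: ", binPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  required <- c("shape", "labels", "pair_ids", "times", "sfreq",
                "channel_ids", "modality", "subject_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L)
    stop("metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  shape <- as.integer(meta$shape)
  nVals <- prod(shape)
  if (file.info(binPath)$size != 8 * nVals)
    stop(sprintf("data file has %d bytes but metadata implies %d (truncated?)",
                 file.info(binPath)$size, 8 * nVals))
  con <- file(binPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = nVals, size = 8L, endian = "little")
  pairIds <- meta$pair_ids
  pairIds[vapply(pairIds, is.null, logical(1L))] <- NA
  EpochsSet(array(vals, dim = shape), labels = meta$labels,
            pairIds = unlist(pairIds), times = meta$times,
            sfreq = meta$sfreq, channelIds = meta$channel_ids,
            modality = meta$modality, subjectId = meta$subject_id)
}

.specFields <- c("nSubjects", "nTrials", "nChannelsMeg", "nChannelsEeg",
                 "sfreq", "tMin", "tMax", "effectLatency", "effectWidth",
                 "effectAmplitude", "effectChannelFraction",
                 "ar1Coefficient", "spatialCorrelationLength",
                 "backgroundNoiseSd", "sensorNoiseSd", "amplitudeSd",
                 "latencyJitterSd", "megScale", "eegScale", "seed")

#' Serialize a SimulationSpec to YAML or JSON
#'
#' @param spec a [SimulationSpec-class].
#' @param path destination; \code{.yaml}/\code{.yml} or \code{.json}.
#' @return the path, invisibly.
#' @export
writeSimulationSpec <- function(spec, path) {
  validObject(spec)
  lst <- lapply(setNames(.specFields, .specFields),
                function(f) slot(spec, f))
  lst$sharedComponents <- apply(spec@sharedComponents, 1L, as.list,
                                simplify = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a SimulationSpec from YAML or JSON
#'
#' @param path a file written by [writeSimulationSpec()].
#' @return a validated [SimulationSpec-class].
#' @export
readSimulationSpec <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- lst$sharedComponents
  shared <- if (is.data.frame(sc)) {
    as.matrix(sc[c("latency", "width", "amplitude")])
  } else {
    do.call(rbind, lapply(sc, function(r)
      unlist(r)[c("latency", "width", "amplitude")]))
  }
  SimulationSpec(nSubjects = lst$nSubjects, nTrials = lst$nTrials,
                 nChannelsMeg = lst$nChannelsMeg,
                 nChannelsEeg = lst$nChannelsEeg, sfreq = lst$sfreq,
                 epochWindow = c(lst$tMin, lst$tMax),
                 effectLatency = lst$effectLatency,
                 effectWidth = lst$effectWidth,
                 effectAmplitude = lst$effectAmplitude,
                 effectChannelFraction = lst$effectChannelFraction,
                 sharedComponents = shared,
                 ar1Coefficient = lst$ar1Coefficient,
                 spatialCorrelationLength = lst$spatialCorrelationLength,
                 backgroundNoiseSd = lst$backgroundNoiseSd,
                 sensorNoiseSd = lst$sensorNoiseSd,
                 amplitudeSd = lst$amplitudeSd,
                 latencyJitterSd = lst$latencyJitterSd,
                 megScale = lst$megScale, eegScale = lst$eegScale,
                 seed = lst$seed)
}

#' Export an AccuracyCurve (or list of curves) to tidy CSV
#'
#' Columns: subject, time_s, accuracy.
#'
#' @param curves an [AccuracyCurve-class] or a list of them.
#' @param path CSV destination.
#' @return the path, invisibly.
#' @export
writeCurvesCsv <- function(curves, path) {
  if (is(curves, "AccuracyCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(c)
    data.frame(subject = subjectId(c), time_s = epochTimes(c),
               accuracy = accuracy(c))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read curves written by [writeCurvesCsv()]
#'
#' Fold detail is not stored in the CSV, so the per-fold matrix of each
#' reconstructed curve is the single mean row.
#'
#' @param path CSV path.
#' @return a list of [AccuracyCurve-class] objects, one per subject.
#' @export
readCurvesCsv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$subject), function(s)
    new("AccuracyCurve", subjectId = as.character(s$subject[1L]),
        times = s$time_s, accuracy = s$accuracy,
        perFold = matrix(s$accuracy, nrow = 1L), configId = "from-csv"))
}

#' Export a GroupResult to tidy CSV
#'
#' Columns: time_s, mean_accuracy, p, significant.
#'
#' @param result a [GroupResult-class].
#' @param path CSV destination.
#' @return the path, invisibly.
#' @export
writeGroupResultCsv <- function(result, path) {
  df <- data.frame(time_s = result@times,
                   mean_accuracy = result@meanAccuracy,
                   p = result@pValues, significant = result@significant)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration id, input and output paths, seeds, package
#' version and a timestamp, so any output can be traced to the exact
#' pipeline that produced it and re-run.
#'
#' @param config a [PipelineConfig-class].
#' @param inputPaths,outputPaths character vectors.
#' @param seeds integer vector of the seeds used.
#' @param path JSON destination.
#' @return the path, invisibly.
#' @export
writeManifest <- function(config, inputPaths, outputPaths, seeds, path) {
  manifest <- list(
    config_id = configId(config),
    input_paths = inputPaths,
    output_paths = outputPaths,
    seeds = seeds,
    software_version = as.character(utils::packageVersion("evokedMVPA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
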