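# One-factor experiment grids: vary a single pipeline choice while
# keeping every other parameter and all seeds fixed, decode every subject
# per level, and run the group-level inference per level.

.gridAxes <- list(
  dr = c("none", "pca", "univariate"),
  subsample = c(NA, 200, 100, 50),
  window = c(NA, 5, 10, 20),
  avg_trials = c(1, 2, 4, 6),
  classifier = c("lda", "ridge", "svm_sigmoid"),
  cv = c(2, 5, 10),
  modality = c("meg", "eeg", "fused")
)

.configForLevel <- function(base, axis, level) {
  cfg <- base
  switch(axis,
    dr = cfg@reducer@method <- as.character(level),
    subsample = cfg@collapse@resampleHz <- as.numeric(level),
    window = cfg@collapse@windowLenMs <- as.numeric(level),
    avg_trials = cfg@collapse@avgGroupSize <- as.integer(level),
    classifier = cfg@classifier@kind <- as.character(level),
    cv = cfg@cvFolds <- as.integer(level))
  validObject(cfg)
  cfg
}

#' Run a one-factor experiment grid over a cohort
#'
#' For each level of the chosen axis, decodes every subject with the base
#' configuration modified only on that axis (seeds shared across levels)
#' and computes the group-level significance against chance. Inputs are
#' never mutated; levels are independent runs over the same epochs.
#'
#' @param cohort list of per-subject entries; each entry either an
#'   [EpochsSet-class] or a list with elements \code{meg} and \code{eeg}
#'   (required for the \code{modality} axis).
#' @param baseConfig a [PipelineConfig-class].
#' @param axis one of \code{"dr"}, \code{"subsample"}, \code{"window"},
#'   \code{"avg_trials"}, \code{"classifier"}, \code{"cv"},
#'   \code{"modality"}.
#' @param levels levels to run; defaults to the canonical set for the
#'   axis. Validated before any computation.
#' @param chance chance accuracy.
#' @param alpha group-test level.
#' @return list with \code{groupResults} (named list of
#'   [GroupResult-class]), \code{curves} (per level) and \code{table} (a
#'   tidy data.frame with columns level, time_s, mean_accuracy, p).
#' @export
runExperimentGrid <- function(cohort, baseConfig, axis,
                              levels = NULL, chance = 0.5, alpha = 0.05) {
  if (!(axis %in% names(.gridAxes)))
    stop("unknown axis: ", axis, "; expected one of ",
         paste(names(.gridAxes), collapse = ", "))
  canonical <- .gridAxes[[axis]]
  if (is.null(levels)) levels <- canonical
  bad <- if (axis %in% c("dr", "classifier", "modality"))
    !(as.character(levels) %in% canonical)
  else
    !(is.na(levels) | suppressWarnings(!is.na(as.numeric(levels))))
  if (any(bad))
    stop("invalid level(s) for axis ", axis, ": ",
         paste(levels[bad], collapse = ", "))
  if (axis == "modality") {
    needs <- vapply(cohort, function(s)
      is.list(s) && all(c("meg", "eeg") %in% names(s)), logical(1L))
    if (!all(needs))
      stop("modality axis requires per-subject meg and eeg epochs")
  }

  levelName <- function(l) if (is.na(l)) "none" else as.character(l)
  groupResults <- list()
  curvesByLevel <- list()
  rows <- list()
  for (l in levels) {
    nm <- levelName(l)
    curves <- lapply(cohort, function(s) {
      if (axis == "modality") {
        E <- switch(as.character(l),
          meg = s$meg, eeg = s$eeg,
          fused = fuseModalities(s$meg, s$eeg, seed = baseConfig@seed))
        decodeTimecourse(E, baseConfig)
      } else {
        E <- if (is(s, "EpochsSet")) s else s$meg
        decodeTimecourse(E, .configForLevel(baseConfig, axis, l))
      }
    })
    gr <- groupSignificance(curves, chance = chance, alpha = alpha)
    groupResults[[nm]] <- gr
    curvesByLevel[[nm]] <- curves
    rows[[nm]] <- data.frame(level = nm, time_s = gr@times,
                             mean_accuracy = gr@meanAccuracy,
                             p = gr@pValues)
  }
  list(groupResults = groupResults, curves = curvesByLevel,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
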