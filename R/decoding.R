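# Time-resolved classification: per-timepoint, per-subject stratified-CV
# decoding with pluggable classifiers, and multimodal fusion.

#' Construct a ClassifierSpec
#'
#' @param kind "lda" (svd solver, no shrinkage), "ridge" (regression on
#'   -1/+1 targets, alpha-regularized, sign-thresholded) or "svm_sigmoid".
#' @param tolerance solver tolerance.
#' @param ridgeAlpha ridge regularization strength.
#' @param svmGamma sigmoid-kernel coefficient; NA means
#'   \code{1 / (n_features * var(features))}.
#' @param svmCoef0 sigmoid-kernel offset.
#' @param svmShrinking use shrinking heuristics in the SVM solver.
#' @param seed classifier seed.
#' @return a validated [ClassifierSpec-class].
#' @export
ClassifierSpec <- function(kind = c("lda", "ridge", "svm_sigmoid"),
                           tolerance = 1e-4, ridgeAlpha = 1,
                           svmGamma = NA_real_, svmCoef0 = 0,
                           svmShrinking = TRUE, seed = 1L) {
  new("ClassifierSpec", kind = match.arg(kind),
      tolerance = as.numeric(tolerance), ridgeAlpha = as.numeric(ridgeAlpha),
      svmGamma = as.numeric(svmGamma), svmCoef0 = as.numeric(svmCoef0),
      svmShrinking = isTRUE(svmShrinking), seed = as.integer(seed))
}

#' Construct a PipelineConfig
#'
#' Defaults mirror the canonical single-trial variant: resampling to
#' 200 Hz, baseline correction over the pre-stimulus interval, PCA
#' retaining 99\% of the variance fitted per fold, LDA, stratified 10-fold
#' cross-validation, chance level 0.5.
#'
#' @param collapse a [CollapseConfig-class].
#' @param reducer a [ReducerSpec-class].
#' @param classifier a [ClassifierSpec-class].
#' @param cvFolds stratified fold count.
#' @param chanceLevel chance accuracy for balanced binary labels.
#' @param seed master seed; stage seeds derive from it.
#' @return a validated [PipelineConfig-class].
#' @export
PipelineConfig <- function(collapse = CollapseConfig(resampleHz = 200),
                           reducer = ReducerSpec("pca"),
                           classifier = ClassifierSpec("lda"),
                           cvFolds = 10L, chanceLevel = 0.5, seed = 1L) {
  new("PipelineConfig", collapse = collapse, reducer = reducer,
      classifier = classifier, cvFolds = as.integer(cvFolds),
      chanceLevel = as.numeric(chanceLevel), seed = as.integer(seed))
}

#' Seeded stratified K-fold partition
#'
#' Shuffles each class once (seeded) and deals it into K folds whose class
#' counts differ by at most one, so every fold preserves the class
#' proportions of the whole set.
#'
#' @param y 0/1 labels.
#' @param k fold count; must not exceed either class count.
#' @param seed shuffle seed.
#' @return integer fold assignment (1..k) per trial.
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts < k))
    stop("cvFolds exceeds the count of at least one class")
  set.seed(seed)
  folds <- integer(length(y))
  for (lab in c(0L, 1L)) {
    idx <- which(y == lab)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Train on (Xtr, ytr), return predicted 0/1 labels for Xte.
.trainPredict <- function(Xtr, ytr, Xte, clf) {
  switch(clf@kind,
    lda = {
      fit <- MASS::lda(Xtr, grouping = factor(ytr, levels = c(0L, 1L)),
                       tol = clf@tolerance)
      as.integer(as.character(predict(fit, Xte)$class))
    },
    ridge = {
      # closed-form ridge on -1/+1 targets, intercept unpenalized
      X1 <- cbind(1, Xtr)
      p <- ncol(X1)
      pen <- diag(c(0, rep(clf@ridgeAlpha, p - 1L)))
      beta <- solve(crossprod(X1) + pen, crossprod(X1, 2 * ytr - 1))
      score <- cbind(1, Xte) %*% beta
      as.integer(score > 0)  # ties (score == 0) -> class 0
    },
    svm_sigmoid = {
      gamma <- clf@svmGamma
      if (is.na(gamma)) {
        v <- mean(apply(Xtr, 2L, var))
        gamma <- if (v > 0) 1 / (ncol(Xtr) * v) else 1 / ncol(Xtr)
      }
      set.seed(clf@seed)
      fit <- e1071::svm(Xtr, factor(ytr, levels = c(0L, 1L)),
                        kernel = "sigmoid", gamma = gamma,
                        coef0 = clf@svmCoef0, tolerance = clf@tolerance,
                        shrinking = clf@svmShrinking, scale = FALSE)
      as.integer(as.character(predict(fit, Xte)))
    },
    stop("unknown classifier kind: ", clf@kind))
}

# Core fold loop shared by timepointDecode and decodeTimecourse.
.decodeFolds <- function(X, y, folds, config) {
  k <- max(folds)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("a fold is missing a class; stratification is broken")
    std <- suppressWarnings(fitStandardizer(X[tr, , drop = FALSE]))
    Xtr <- applyStandardizer(std, X[tr, , drop = FALSE])
    Xte <- applyStandardizer(std, X[te, , drop = FALSE])
    if (config@reducer@method == "pca") {
      red <- pcaReduce(Xtr, Xte, config@reducer@pcaVarThreshold)
      Xtr <- red$train
      Xte <- red$test
    }
    pred <- .trainPredict(Xtr, y[tr], Xte, config@classifier)
    acc[f] <- mean(pred == y[te])
  }
  acc
}

#' Decode one timepoint under stratified cross-validation
#'
#' Builds a seeded stratified K-fold partition and, per fold, fits the
#' standardizer and reducer on training rows only, trains the configured
#' classifier, and scores the held-out fold.
#'
#' @param X trials x features matrix.
#' @param y 0/1 labels (balanced or near-balanced).
#' @param config a [PipelineConfig-class].
#' @return numeric vector of K fold accuracies.
#' @export
timepointDecode <- function(X, y, config) {
  folds <- stratifiedFolds(y, config@cvFolds, seed = config@seed)
  .decodeFolds(X, as.integer(y), folds, config)
}

#' Time-resolved decoding of one subject
#'
#' Applies the full pipeline: class balancing, the time-axis collapse
#' steps of the config, pseudo-trial averaging, optional univariate
#' channel selection, then per-timepoint stratified-CV decoding. One
#' seeded CV partition is used for all timepoints. Deterministic given the
#' config seed.
#'
#' @param E an [EpochsSet-class].
#' @param config a [PipelineConfig-class].
#' @return an [AccuracyCurve-class].
#' @export
decodeTimecourse <- function(E, config) {
  E <- balanceEpochs(E, seed = .deriveSeed(config@seed, 1L))
  E <- collapseTime(E, config@collapse)
  if (config@collapse@avgGroupSize > 1L)
    E <- averageTrials(E, config@collapse@avgGroupSize,
                       seed = .deriveSeed(config@seed, 2L))
  if (config@reducer@method == "univariate") {
    mask <- univariateSelectChannels(E, config@reducer)
    if (!any(mask)) {
      warning("empty channel selection; falling back to all channels")
      mask <- rep(TRUE, nChannels(E))
    }
    E@data <- E@data[, mask, , drop = FALSE]
    E@channelIds <- E@channelIds[mask]
  }
  y <- trialLabels(E)
  folds <- stratifiedFolds(y, config@cvFolds,
                           seed = .deriveSeed(config@seed, 3L))
  d <- dim(E@data)
  perFold <- matrix(0, config@cvFolds, d[3L])
  for (t in seq_len(d[3L])) {
    X <- E@data[, , t, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    perFold[, t] <- .decodeFolds(X, y, folds, config)
  }
  new("AccuracyCurve", subjectId = subjectId(E), times = epochTimes(E),
      accuracy = colMeans(perFold), perFold = perFold,
      configId = configId(config))
}

#' Fuse two modalities of one subject into a single feature space
#'
#' Trials are matched across modalities by (pair id, label), the matched
#' set is balanced, each channel is scaled to unit variance over the whole
#' epoch set (all trials and timepoints), and the channel axes are
#' concatenated.
#'
#' @param eMeg,eEeg [EpochsSet-class] objects of the same subject on the
#'   same time grid (resample first if needed).
#' @param seed balancing seed.
#' @return a fused [EpochsSet-class] (modality \code{"fused"}).
#' @export
fuseModalities <- function(eMeg, eEeg, seed = 1L) {
  if (length(epochTimes(eMeg)) != length(epochTimes(eEeg)) ||
      max(abs(epochTimes(eMeg) - epochTimes(eEeg))) > 1e-9)
    stop("time grids differ; resample to a common grid first")
  keyM <- paste(pairIds(eMeg), trialLabels(eMeg))
  keyE <- paste(pairIds(eEeg), trialLabels(eEeg))
  okM <- !is.na(pairIds(eMeg))
  okE <- !is.na(pairIds(eEeg))
  common <- intersect(keyM[okM], keyE[okE])
  if (length(common) == 0L)
    stop("no trials shared across modalities (empty pair/label intersection)")
  iM <- match(common, keyM)
  iE <- match(common, keyE)
  m <- eMeg[iM]
  e <- eEeg[iE]
  m <- balanceEpochs(m, seed = seed)
  e <- e[match(paste(pairIds(m), trialLabels(m)),
               paste(pairIds(e), trialLabels(e)))]
  unitVar <- function(E) {
    d <- dim(E@data)
    for (ch in seq_len(d[2L])) {
      v <- sd(as.vector(E@data[, ch, ]))
      if (v > 0) E@data[, ch, ] <- E@data[, ch, ] / v
    }
    E
  }
  m <- unitVar(m)
  e <- unitVar(e)
  d <- dim(m@data)
  dE <- dim(e@data)
  data <- array(0, dim = c(d[1L], d[2L] + dE[2L], d[3L]))
  data[, seq_len(d[2L]), ] <- m@data
  data[, d[2L] + seq_len(dE[2L]), ] <- e@data
  EpochsSet(data, labels = trialLabels(m), pairIds = pairIds(m),
            times = epochTimes(m), sfreq = samplingRate(m),
            channelIds = c(channelIds(m), channelIds(e)),
            modality = "fused", subjectId = subjectId(m))
}
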