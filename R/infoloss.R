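# Mutual-information procedure quantifying the information retained after
# a reduction operation: Gaussian-mixture density fits selected by AIC,
# Monte-Carlo sampling from the joint fit, and the Kraskov (KSG)
# k-nearest-neighbour MI estimate on the sampled pairs, with a
# density-ratio estimate kept as a diagnostic and a closed-form Gaussian
# oracle for validation.

#' Closed-form mutual information of a joint Gaussian
#'
#' For a positive-definite joint covariance over (X, Y), returns
#' \deqn{I(X;Y) = (log det S_X + log det S_Y - log det S_{XY}) / 2}
#' in nats. Serves as the analytic oracle for the sampling estimator.
#'
#' @param jointCovariance (dX + dY) square covariance matrix.
#' @param dX,dY block dimensions.
#' @return mutual information in nats.
#' @examples
#' S <- matrix(c(1, 0.9, 0.9, 1), 2)
#' gaussianMiClosedForm(S, 1, 1)  # -0.5 * log(1 - 0.81)
#' @export
gaussianMiClosedForm <- function(jointCovariance, dX, dY) {
  S <- as.matrix(jointCovariance)
  if (nrow(S) != dX + dY)
    stop("joint covariance must be (dX + dY) square")
  logdet <- function(M) {
    ch <- tryCatch(chol(M), error = function(e)
      stop("covariance is not positive definite"))
    2 * sum(log(diag(ch)))
  }
  ix <- seq_len(dX)
  iy <- dX + seq_len(dY)
  0.5 * (logdet(S[ix, ix, drop = FALSE]) +
         logdet(S[iy, iy, drop = FALSE]) - logdet(S))
}

#' Fit a Gaussian mixture with AIC model selection
#'
#' Fits one mixture per candidate component count and keeps the fit with
#' minimum AIC. Full covariances are the default; diagonal covariances are
#' enforced when there are fewer observations than dimensions. Mixture
#' fitting is initialized from a seeded subset, so the fit is
#' deterministic given the seed.
#'
#' @param samples observations x d matrix (a vector is treated as 1-d).
#' @param kCandidates candidate component counts.
#' @param covarianceType "full" or "diagonal".
#' @param seed initialization seed.
#' @return a \code{gmmDensity} object exposing log-density and sampling
#'   via [gmmLogDensity()] and [gmmSample()]; the AIC table is attached.
#' @export
fitGmmAic <- function(samples, kCandidates = 1:10,
                      covarianceType = c("full", "diagonal"), seed = 1L) {
  covarianceType <- match.arg(covarianceType)
  X <- as.matrix(samples)
  n <- nrow(X)
  d <- ncol(X)
  if (n <= d && covarianceType == "full")
    covarianceType <- "diagonal"
  modelName <- if (d == 1L) "V"
    else if (covarianceType == "full") "VVV" else "VVI"
  set.seed(seed)
  initSub <- if (n > 1000L) sort(sample.int(n, 1000L)) else seq_len(n)
  fits <- list()
  aics <- rep(NA_real_, length(kCandidates))
  for (i in seq_along(kCandidates)) {
    g <- kCandidates[i]
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(X, G = g, modelNames = modelName,
                                      initialization = list(subset = initSub),
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik))
      next
    npar <- mclust::nMclustParams(modelName, d, g)
    aics[i] <- -2 * fit$loglik + 2 * npar
    fits[[i]] <- fit
  }
  if (all(is.na(aics))) {
    if (covarianceType == "full")
      stop("mixture fit singular at every candidate; try diagonal covariance")
    stop("mixture fit failed at every candidate component count")
  }
  best <- which.min(aics)
  structure(list(modelName = modelName, d = d,
                 G = kCandidates[best],
                 parameters = fits[[best]]$parameters,
                 aic = setNames(aics, kCandidates),
                 loglik = fits[[best]]$loglik),
            class = "gmmDensity")
}

# Single-component fits store covariance factors as plain matrices; the
# mclust simulation/density helpers expect d x d x G arrays.
.normalizeGmmParams <- function(model) {
  p <- model$parameters
  v <- p$variance
  for (nm in c("cholsigma", "sigma")) {
    if (!is.null(v[[nm]]) && model$d > 1L &&
        length(dim(v[[nm]])) == 2L)
      p$variance[[nm]] <- array(v[[nm]], c(dim(v[[nm]]), 1L))
  }
  p
}

#' Log-density under a fitted Gaussian mixture
#'
#' @param model a \code{gmmDensity} from [fitGmmAic()].
#' @param x observations x d matrix.
#' @return log-density per row, nats.
#' @export
gmmLogDensity <- function(model, x) {
  x <- as.matrix(x)
  if (model$d == 1L) x <- as.vector(x)
  mclust::dens(data = x, modelName = model$modelName,
               parameters = .normalizeGmmParams(model), logarithm = TRUE)
}

#' Draw samples from a fitted Gaussian mixture
#'
#' @param model a \code{gmmDensity} from [fitGmmAic()].
#' @param n sample count.
#' @param seed seed.
#' @return n x d matrix of draws.
#' @export
gmmSample <- function(model, n, seed = 1L) {
  set.seed(seed)
  s <- mclust::sim(modelName = model$modelName,
                   parameters = .normalizeGmmParams(model), n = n)
  as.matrix(s[, -1L, drop = FALSE])  # first column is the component label
}

#' @export
print.gmmDensity <- function(x, ...) {
  cat(sprintf("gmmDensity: %d-component %s mixture in %d dims (AIC %.1f)\n",
              x$G, x$modelName, x$d, min(x$aic, na.rm = TRUE)))
  invisible(x)
}

#' Kraskov (KSG) k-nearest-neighbour mutual information
#'
#' First KSG estimator: with max-norm distances, for each point the
#' distance to its k-th neighbour in the joint space sets a radius, and
#' the marginal neighbour counts inside that radius enter
#' \deqn{I = psi(k) + psi(N) - < psi(n_x + 1) + psi(n_y + 1) >.}
#' Distances are computed in row chunks to bound memory.
#'
#' @param x,y observation-aligned matrices (vectors treated as 1-d).
#' @param k neighbour count.
#' @return mutual information in nats (can be slightly negative for
#'   independent data; callers clip where a nonnegative report is needed).
#' @export
ksgMutualInformation <- function(x, y, k = 3L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have equal row counts")
  if (k >= n) stop("k must be smaller than the number of observations")
  chebDist <- function(A, rows) {
    D <- abs(outer(A[rows, 1L], A[, 1L], "-"))
    if (ncol(A) > 1L)
      for (j in 2:ncol(A)) D <- pmax(D, abs(outer(A[rows, j], A[, j], "-")))
    D
  }
  chunk <- max(16L, floor(4e6 / n))
  psiSum <- 0
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    dx <- chebDist(x, rows)
    dy <- chebDist(y, rows)
    dj <- pmax(dx, dy)
    eps <- apply(dj, 1L, function(v) sort.int(v, partial = k + 1L)[k + 1L])
    # eps recycles down columns: each column is compared entry-wise
    nx <- rowSums(dx < eps) - 1L
    ny <- rowSums(dy < eps) - 1L
    psiSum <- psiSum + sum(digamma(nx + 1) + digamma(ny + 1))
  }
  digamma(k) + digamma(n) - psiSum / n
}

# Normalize the many ways a reduction operation can be described into
# list(type=..., dimension=..., ...).
.normalizeReduction <- function(operation) {
  if (is(operation, "CollapseConfig")) {
    if (operation@avgGroupSize > 1L)
      return(list(type = "averageTrials", dimension = "trial",
                  groupSize = operation@avgGroupSize,
                  seed = operation@seed))
    if (!is.na(operation@resampleHz))
      return(list(type = "resample", dimension = "temporal",
                  targetHz = operation@resampleHz))
    if (!is.na(operation@windowLenMs))
      return(list(type = "slidingWindow", dimension = "temporal",
                  windowLenMs = operation@windowLenMs,
                  stepFraction = operation@windowStepFraction))
    stop("CollapseConfig describes no reduction operation")
  }
  if (is(operation, "ReducerSpec")) {
    if (operation@method == "pca")
      return(list(type = "pca", dimension = "channel",
                  varThreshold = operation@pcaVarThreshold))
    if (operation@method == "univariate")
      return(list(type = "univariate", dimension = "channel",
                  spec = operation))
    stop("ReducerSpec 'none' describes no reduction operation")
  }
  if (is.list(operation) && !is.null(operation$type)) {
    operation$dimension <- switch(operation$type,
      pca = , channelMask = , univariate = "channel",
      averageTrials = "trial",
      resample = , slidingWindow = "temporal",
      stop("unsupported reduction operation: ", operation$type))
    return(operation)
  }
  stop("unsupported reduction operation")
}

#' Build paired benchmark/reduced observation sets
#'
#' The observation unit is one (trial, timepoint) sample. The benchmark
#' feature is the full channel vector at that sample; the operated feature
#' is the representation the reduction assigns to the same sample: the
#' reduced channel vector (channel-dimension operations), the pseudo-trial
#' vector of the group containing the trial (trial averaging), or the
#' vector at the decimated timepoint / sliding window containing the
#' sample (temporal operations). Rows are aligned one-to-one and
#' optionally subsampled (seeded) to a cap.
#'
#' @param E an [EpochsSet-class].
#' @param operation a [CollapseConfig-class], a [ReducerSpec-class], or a
#'   list such as \code{list(type = "pca", nComponents = 10)},
#'   \code{list(type = "channelMask", mask = m)},
#'   \code{list(type = "averageTrials", groupSize = 2)},
#'   \code{list(type = "resample", targetHz = 200)} or
#'   \code{list(type = "slidingWindow", windowLenMs = 10)}.
#' @param maxObservations subsampling cap on observation rows.
#' @param seed subsampling (and grouping) seed.
#' @return a [ReductionPair-class].
#' @export
buildReductionPairs <- function(E, operation, maxObservations = 20000L,
                                seed = 1L) {
  op <- .normalizeReduction(operation)
  d <- dim(E@data)
  nTr <- d[1L]; nCh <- d[2L]; nT <- d[3L]
  # benchmark: observation rows in (trial, time) order, trial fastest
  bench <- matrix(aperm(E@data, c(1L, 3L, 2L)), ncol = nCh)
  obsTrial <- rep_len(seq_len(nTr), nTr * nT)
  obsTime <- rep(seq_len(nT), each = nTr)

  operated <- switch(op$type,
    pca = {
      mu <- colMeans(bench)
      sv <- svd(sweep(bench, 2L, mu), nu = 0)
      m <- if (!is.null(op$nComponents)) op$nComponents else {
        ev <- sv$d^2
        which(cumsum(ev) / sum(ev) >= op$varThreshold - 1e-12)[1L]
      }
      sweep(bench, 2L, mu) %*% sv$v[, seq_len(m), drop = FALSE]
    },
    channelMask = bench[, op$mask, drop = FALSE],
    univariate = {
      mask <- univariateSelectChannels(E, op$spec)
      if (!any(mask)) stop("univariate selection kept no channels")
      bench[, mask, drop = FALSE]
    },
    averageTrials = {
      ps <- averageTrials(E, op$groupSize,
                          seed = if (!is.null(op$seed)) op$seed else seed,
                          returnGroups = TRUE)
      groups <- attr(ps, "groups")
      groupOf <- rep(NA_integer_, nTr)
      for (g in seq_along(groups)) groupOf[groups[[g]]] <- g
      keep <- !is.na(groupOf[obsTrial])
      bench <- bench[keep, , drop = FALSE]
      psd <- epochsData(ps)
      out <- matrix(0, sum(keep), nCh)
      gi <- groupOf[obsTrial[keep]]
      ti <- obsTime[keep]
      for (r in seq_len(nrow(out))) out[r, ] <- psd[gi[r], , ti[r]]
      out
    },
    resample = {
      res <- resampleEpochs(E, op$targetHz)
      factor <- round(E@sfreq / op$targetHz)
      j <- (obsTime - 1L) %/% factor + 1L
      keep <- j <= nTimepoints(res)
      bench <- bench[keep, , drop = FALSE]
      rd <- epochsData(res)
      out <- matrix(0, sum(keep), nCh)
      jj <- j[keep]; tr <- obsTrial[keep]
      for (r in seq_len(nrow(out))) out[r, ] <- rd[tr[r], , jj[r]]
      out
    },
    slidingWindow = {
      stepFraction <- if (!is.null(op$stepFraction)) op$stepFraction else 0.6
      win <- slidingWindowAverage(E, op$windowLenMs, stepFraction)
      L <- round(op$windowLenMs / 1000 * E@sfreq)
      step <- max(1L, round(stepFraction * L))
      starts <- seq(1L, nT - L + 1L, by = step)
      centers <- starts + (L - 1) / 2
      wOf <- vapply(obsTime, function(t) {
        cand <- which(starts <= t & t <= starts + L - 1L)
        if (length(cand) == 0L) return(NA_integer_)
        cand[which.min(abs(centers[cand] - t))]
      }, integer(1L))
      keep <- !is.na(wOf)
      bench <- bench[keep, , drop = FALSE]
      wd <- epochsData(win)
      out <- matrix(0, sum(keep), nCh)
      wi <- wOf[keep]; tr <- obsTrial[keep]
      for (r in seq_len(nrow(out))) out[r, ] <- wd[tr[r], , wi[r]]
      out
    },
    stop("unsupported reduction operation: ", op$type))

  if (nrow(bench) > maxObservations) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(bench), maxObservations))
    bench <- bench[keep, , drop = FALSE]
    operated <- operated[keep, , drop = FALSE]
  }
  new("ReductionPair", benchmark = bench, operated = operated,
      dimension = op$dimension,
      mapping = paste(op$type,
                      paste(vapply(op[!(names(op) %in%
                                        c("type", "dimension", "spec",
                                          "mask"))],
                                   function(v) paste(format(v),
                                                     collapse = ","),
                                   character(1L)),
                            collapse = ";")),
      subjectId = subjectId(E))
}

#' Estimate the mutual information of a reduction pair
#'
#' Fits AIC-selected Gaussian mixtures to the benchmark rows, the operated
#' rows and their joint concatenation; per repeat, draws
#' \code{nMcSamples} points from the joint mixture, records the
#' density-ratio estimate \code{mean(log pJ - log pX - log pY)} as a
#' diagnostic, and takes the KSG k-nearest-neighbour estimate on the same
#' sampled pairs as the repeat's MI. The final value is the repeat mean,
#' clipped at 0 from below. The mixture fits are deterministic given the
#' data and seed, so only the Monte-Carlo sampling varies across repeats.
#'
#' @param pair a [ReductionPair-class].
#' @param nMcSamples Monte-Carlo draws per repeat (>= 100).
#' @param kNn KSG neighbour count.
#' @param repeats number of Monte-Carlo repeats averaged.
#' @param seed master seed.
#' @param kCandidates candidate mixture sizes for [fitGmmAic()].
#' @param covarianceType "full" or "diagonal" mixture covariances.
#' @return an [MIResult-class].
#' @export
estimateMi <- function(pair, nMcSamples = 10000L, kNn = 3L, repeats = 10L,
                       seed = 1L, kCandidates = 1:10,
                       covarianceType = "full") {
  if (nMcSamples < 100L) stop("nMcSamples must be >= 100")
  X <- pair@benchmark
  Y <- pair@operated
  dX <- ncol(X)
  dY <- ncol(Y)
  if (all(apply(Y, 2L, var) == 0)) {
    warning("operated data are degenerate (zero variance); MI = 0")
    return(new("MIResult", miPerRepeat = rep(0, repeats), miMean = 0,
               miDensityPerRepeat = rep(0, repeats),
               nComponentsX = 0L, nComponentsY = 0L, nComponentsJoint = 0L,
               nMcSamples = as.integer(nMcSamples), kNn = as.integer(kNn),
               seed = as.integer(seed)))
  }
  gx <- fitGmmAic(X, kCandidates, covarianceType,
                  seed = .deriveSeed(seed, 11L))
  gy <- fitGmmAic(Y, kCandidates, covarianceType,
                  seed = .deriveSeed(seed, 12L))
  gj <- fitGmmAic(cbind(X, Y), kCandidates, covarianceType,
                  seed = .deriveSeed(seed, 13L))
  miKnn <- numeric(repeats)
  miDens <- numeric(repeats)
  for (r in seq_len(repeats)) {
    S <- gmmSample(gj, nMcSamples, seed = .deriveSeed(seed, 100L + r))
    xs <- S[, seq_len(dX), drop = FALSE]
    ys <- S[, dX + seq_len(dY), drop = FALSE]
    miDens[r] <- mean(gmmLogDensity(gj, S) - gmmLogDensity(gx, xs) -
                      gmmLogDensity(gy, ys))
    miKnn[r] <- ksgMutualInformation(xs, ys, k = kNn)
  }
  new("MIResult", miPerRepeat = miKnn, miMean = max(0, mean(miKnn)),
      miDensityPerRepeat = miDens,
      nComponentsX = as.integer(gx$G), nComponentsY = as.integer(gy$G),
      nComponentsJoint = as.integer(gj$G),
      nMcSamples = as.integer(nMcSamples), kNn = as.integer(kNn),
      seed = as.integer(seed))
}

#' Pearson correlation between MI and accuracy differences
#'
#' Computes the Pearson correlation between per-subject MI values and
#' decoding-accuracy differences (peak group-mean accuracy under the
#' operation minus the no-operation peak), with the two-sided p-value from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param miValues numeric vector.
#' @param accuracyDifferences numeric vector, same length (n >= 3).
#' @param xLabel,yLabel variable names for reporting.
#' @return a [CorrelationResult-class].
#' @export
miAccuracyCorrelation <- function(miValues, accuracyDifferences,
                                  xLabel = "MI",
                                  yLabel = "accuracy difference") {
  x <- as.numeric(miValues)
  y <- as.numeric(accuracyDifferences)
  if (length(x) != length(y) || length(x) < 3L)
    stop("paired inputs of length >= 3 are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in an input; correlation undefined")
  n <- length(x)
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  new("CorrelationResult", r = r, p = p, n = as.integer(n),
      xLabel = xLabel, yLabel = yLabel)
}

#' Pairwise Welch t-tests on MI across reduction dimensions
#'
#' @param miByDimension named list of numeric vectors (>= 2 values each),
#'   e.g. \code{list(channel = ..., trial = ..., temporal = ...)}.
#' @return data.frame with columns dimA, dimB, t, p (two-sided Welch).
#' @export
miDimensionTtests <- function(miByDimension) {
  dims <- names(miByDimension)
  if (any(vapply(miByDimension, length, integer(1L)) < 2L))
    stop("each dimension needs at least 2 values")
  pairs <- utils::combn(dims, 2L)
  out <- data.frame(dimA = character(0), dimB = character(0),
                    t = numeric(0), p = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    a <- miByDimension[[pairs[1L, j]]]
    b <- miByDimension[[pairs[2L, j]]]
    res <- if (var(a) + var(b) == 0) {
      # degenerate (constant) groups: t = 0, p = 1 when the means agree
      if (mean(a) == mean(b)) c(0, 1) else c(sign(mean(a) - mean(b)) * Inf, 0)
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      c(unname(tt$statistic), tt$p.value)
    }
    out <- rbind(out, data.frame(dimA = pairs[1L, j], dimB = pairs[2L, j],
                                 t = res[1L], p = res[2L]))
  }
  out
}
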