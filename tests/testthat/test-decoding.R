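test_that("stratified folds preserve class proportions for all tested (n, K)", {
  for (n in c(24, 96, 192)) {
    for (K in c(2, 5, 10)) {
      y <- rep(c(0L, 1L), each = n / 2)
      f <- stratifiedFolds(y, K, seed = n + K)
      expect_equal(sort(unique(f)), 1:K)
      counts <- table(f, y)
      expect_lte(max(counts[, 1]) - min(counts[, 1]), 1)
      expect_lte(max(counts[, 2]) - min(counts[, 2]), 1)
      # within every fold the class counts differ by at most 1
      expect_lte(max(abs(counts[, 1] - counts[, 2])), 1)
    }
  }
  expect_error(stratifiedFolds(rep(c(0L, 1L), each = 4), 10), "exceeds")
})

test_that("widely separated classes decode perfectly with every classifier", {
  set.seed(21)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(rnorm(n, mean = ifelse(y == 1, 10, -10)), rnorm(n))
  for (kind in c("lda", "ridge")) {
    cfg <- PipelineConfig(classifier = ClassifierSpec(kind),
                          reducer = ReducerSpec("none"), cvFolds = 5L)
    acc <- timepointDecode(X, y, cfg)
    expect_equal(acc, rep(1, 5))
  }
  # the sigmoid kernel gives no separability guarantee; it must still be
  # far above chance on this input
  cfgS <- PipelineConfig(classifier = ClassifierSpec("svm_sigmoid"),
                         reducer = ReducerSpec("none"), cvFolds = 5L)
  expect_gt(mean(timepointDecode(X, y, cfgS)), 0.8)
})

test_that("chance-level data decode at chance", {
  set.seed(22)
  accs <- replicate(100, {
    y <- rep(c(0L, 1L), each = 100)
    X <- matrix(rnorm(200 * 4), 200, 4)
    cfg <- PipelineConfig(reducer = ReducerSpec("none"), cvFolds = 10L,
                          seed = sample.int(1e6, 1))
    mean(timepointDecode(X, y, cfg))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})

test_that("ridge breaks score ties toward class 0", {
  # symmetric training data, query exactly on the boundary
  Xtr <- matrix(c(-1, -1, 1, 1), 4, 1)
  ytr <- c(0L, 0L, 1L, 1L)
  pred <- evokedMVPA:::.trainPredict(Xtr, ytr, matrix(0, 1, 1),
                                     ClassifierSpec("ridge"))
  expect_equal(pred, 0L)
})

test_that("decoding is invariant to trial order under a fixed partition", {
  set.seed(23)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3)
  X[y == 1L, 1] <- X[y == 1L, 1] + 1
  cfg <- PipelineConfig(reducer = ReducerSpec("none"), cvFolds = 5L)
  folds <- stratifiedFolds(y, 5, seed = 1)
  a1 <- evokedMVPA:::.decodeFolds(X, y, folds, cfg)
  perm <- sample.int(n)
  a2 <- evokedMVPA:::.decodeFolds(X[perm, ], y[perm], folds[perm], cfg)
  expect_equal(a1, a2)
})

test_that("decodeTimecourse ties the stages together reproducibly", {
  spec <- SimulationSpec(nSubjects = 1L, nTrials = 32L, nChannelsMeg = 6L,
                         nChannelsEeg = 6L, sfreq = 50,
                         effectAmplitude = 0.8)
  e <- generateSubject(spec, 1, modalities = "meg")$meg
  cfg <- PipelineConfig(collapse = CollapseConfig(), cvFolds = 4L)
  c1 <- decodeTimecourse(e, cfg)
  c2 <- decodeTimecourse(e, cfg)
  expect_identical(accuracy(c1), accuracy(c2))
  expect_equal(accuracy(c1), colMeans(perFold(c1)))
  expect_equal(length(accuracy(c1)), nTimepoints(e))
  expect_equal(subjectId(c1), "sub-01")
  # pseudo-trial averaging path changes the CV unit count, not the grid
  cfgA <- PipelineConfig(collapse = CollapseConfig(avgGroupSize = 2L),
                         cvFolds = 4L)
  cA <- decodeTimecourse(e, cfgA)
  expect_equal(length(accuracy(cA)), nTimepoints(e))
})

test_that("fusion matches trials, scales channels and concatenates features", {
  spec <- SimulationSpec(nSubjects = 1L, nTrials = 24L, nChannelsMeg = 5L,
                         nChannelsEeg = 7L, sfreq = 50)
  s <- generateSubject(spec, 1)
  f <- fuseModalities(s$meg, s$eeg, seed = 1)
  expect_equal(nChannels(f), 12L)
  expect_equal(modality(f), "fused")
  expect_equal(nTrials(f), 24L)
  sds <- vapply(seq_len(12), function(ch)
    sd(as.vector(epochsData(f)[, ch, ])), numeric(1))
  expect_lt(max(abs(sds - 1)), 1e-9)
  # fused rows carry matched labels: same pair/label composition
  expect_true(all(table(pairIds(f), trialLabels(f)) <= 1))

  bad <- resampleEpochs(s$eeg, 25)
  expect_error(fuseModalities(s$meg, bad), "time grids")
})

test_that("fusing in a pure-noise modality barely changes decoding", {
  diffs <- vapply(1:20, function(r) {
    spec <- SimulationSpec(nSubjects = 1L, nTrials = 48L,
                           nChannelsMeg = 4L, nChannelsEeg = 4L,
                           sfreq = 50, epochWindow = c(-0.2, 0.8),
                           effectAmplitude = 0.5, seed = 300L + r)
    s <- generateSubject(spec, 1)
    noise <- s$eeg
    set.seed(900 + r)
    noise@data[] <- rnorm(length(noise@data))
    fused <- fuseModalities(s$meg, noise, seed = r)
    cfg <- PipelineConfig(collapse = CollapseConfig(),
                          reducer = ReducerSpec("none"), cvFolds = 5L,
                          seed = r)
    mean(accuracy(decodeTimecourse(fused, cfg)) -
         accuracy(decodeTimecourse(s$meg, cfg)))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.03)
})
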