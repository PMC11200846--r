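test_that("Gaussian closed form reproduces textbook values", {
  expect_equal(gaussianMiClosedForm(diag(4), 2, 2), 0)
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(gaussianMiClosedForm(S, 1, 1), -0.5 * log(1 - 0.81))
  # block-diagonal joint: independent blocks
  B <- rbind(cbind(matrix(c(2, 0.5, 0.5, 1), 2), matrix(0, 2, 1)),
             cbind(matrix(0, 1, 2), 3))
  expect_equal(gaussianMiClosedForm(B, 2, 1), 0)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(gaussianMiClosedForm(bad, 1, 1), "positive definite")
})

test_that("AIC selects the generating component count", {
  sel <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(3000 * 2), ncol = 2)
    fitGmmAic(X, kCandidates = 1:5, seed = s)$G
  }, integer(1))
  expect_gte(mean(sel == 1L), 0.9)

  set.seed(3)
  X2 <- rbind(matrix(rnorm(2000), ncol = 2),
              matrix(rnorm(2000) + 10, ncol = 2))
  expect_equal(fitGmmAic(X2, kCandidates = 1:5, seed = 1)$G, 2L)
})

test_that("single-component fit matches the closed-form Gaussian density", {
  set.seed(5)
  X <- matrix(rnorm(5000 * 2), ncol = 2)
  g <- fitGmmAic(X, kCandidates = 1, seed = 1)
  mu <- colMeans(X)
  ld <- gmmLogDensity(g, matrix(mu, 1))
  S <- cov(X) * (nrow(X) - 1) / nrow(X)  # ML covariance
  ref <- -log(2 * pi) - 0.5 * determinant(S)$modulus[1]
  expect_equal(as.numeric(ld), as.numeric(ref), tolerance = 0.01)
  # sampling is seeded and matches the model dimension
  s1 <- gmmSample(g, 100, seed = 9)
  expect_equal(dim(s1), c(100L, 2L))
  expect_identical(s1, gmmSample(g, 100, seed = 9))
})

test_that("KSG estimator tracks the Gaussian closed form", {
  set.seed(6)
  n <- 4000
  x <- rnorm(n)
  yInd <- rnorm(n)
  expect_lt(abs(ksgMutualInformation(x, yInd, 3)), 0.05)
  y5 <- 0.5 * x + sqrt(0.75) * rnorm(n)
  expect_lt(abs(ksgMutualInformation(x, y5, 3) - 0.1438), 0.05)
})

test_that("reduction pairs align observations with their reduced images", {
  e <- whiteNoiseEpochs(nTrials = 8, nCh = 6, nT = 10, seed = 41)
  # identity channel mask
  idp <- buildReductionPairs(e, list(type = "channelMask", mask = rep(TRUE, 6)))
  expect_identical(idp@benchmark, idp@operated)
  expect_equal(idp@dimension, "channel")

  pca <- buildReductionPairs(e, list(type = "pca", nComponents = 3))
  expect_equal(ncol(pca@benchmark), 6L)
  expect_equal(ncol(pca@operated), 3L)
  expect_equal(nrow(pca@benchmark), nrow(pca@operated))

  # trial averaging: each operated row is the pseudo-trial of its group
  avg <- buildReductionPairs(e, list(type = "averageTrials", groupSize = 2,
                                     seed = 7))
  expect_equal(avg@dimension, "trial")
  expect_equal(nrow(avg@benchmark), 8 * 10)
  ps <- averageTrials(e, 2, seed = 7, returnGroups = TRUE)
  groups <- attr(ps, "groups")
  # the operated rows of the two member trials of one group are identical
  g1 <- groups[[1]]
  rows <- which(rep_len(seq_len(8), 80) %in% g1 &
                rep(seq_len(10), each = 8) == 1)
  expect_equal(avg@operated[rows[1], ], avg@operated[rows[2], ])
  expect_equal(avg@operated[rows[1], ],
               colMeans(epochsData(e)[g1, , 1]))

  # temporal: the operated row is the decimated timepoint containing it
  et <- whiteNoiseEpochs(nTrials = 4, nCh = 3, nT = 40, sfreq = 100,
                         seed = 42)
  res <- buildReductionPairs(et, list(type = "resample", targetHz = 50))
  expect_equal(res@dimension, "temporal")
  rEp <- resampleEpochs(et, 50)
  # sample (trial 2, time 3) maps to decimated index 2
  row <- which(rep_len(seq_len(4), 160) == 2 &
               rep(seq_len(40), each = 4) == 3)
  expect_equal(res@operated[row, ], epochsData(rEp)[2, , 2])

  # observation cap subsamples both sides together
  cap <- buildReductionPairs(e, list(type = "channelMask",
                                     mask = rep(TRUE, 6)),
                             maxObservations = 30, seed = 2)
  expect_equal(nrow(cap@benchmark), 30L)
  expect_identical(cap@benchmark, cap@operated)

  expect_error(buildReductionPairs(e, list(type = "fourier")), "unsupported")
})

test_that("degenerate operated data yield MI = 0 with a warning", {
  pair <- new("ReductionPair", benchmark = matrix(rnorm(200), 100, 2),
              operated = matrix(1, 100, 1), dimension = "channel",
              mapping = "m", subjectId = "s")
  expect_warning(r <- estimateMi(pair, nMcSamples = 200, repeats = 2),
                 "degenerate")
  expect_equal(miMean(r), 0)
  expect_error(estimateMi(pair, nMcSamples = 50), "100")
})

test_that("nested reductions do not gain information", {
  # data-processing trend on Gaussian data: MI(X; R2 R1 X) stays within
  # estimator noise of or below MI(X; R1 X)
  set.seed(44)
  delta <- vapply(1:20, function(r) {
    n <- 800
    X <- matrix(rnorm(n * 3), n, 3)
    R1 <- X[, 1:2] + 0.3 * matrix(rnorm(n * 2), n, 2)  # keep 2 coords
    R2 <- R1[, 1, drop = FALSE]                        # then keep 1
    ksgMutualInformation(X, R2, 3) - ksgMutualInformation(X, R1, 3)
  }, numeric(1))
  expect_lte(mean(delta), 0.05)
})

test_that("Pearson correlation matches the t-distribution formula", {
  x <- 1:6
  expect_equal(miAccuracyCorrelation(x, 2 * x + 1)@r, 1)
  expect_equal(miAccuracyCorrelation(x, 2 * x + 1)@p, 0)

  # construct a 6-point set with r = 0.8 exactly
  sx <- scale(x)[, 1]
  e <- c(1, -1, 0.5, -0.5, 0.25, -0.25)
  e <- resid(lm(e ~ sx))
  e <- e / sqrt(sum(e^2))
  y <- 0.8 * sx / sqrt(sum(sx^2)) + 0.6 * e
  res <- miAccuracyCorrelation(x, y)
  expect_equal(res@r, 0.8, tolerance = 1e-9)
  tref <- 0.8 * sqrt(4 / (1 - 0.64))
  expect_equal(res@p, 2 * pt(tref, df = 4, lower.tail = FALSE),
               tolerance = 1e-9)
  # independent oracle
  ct <- cor.test(x, y)
  expect_equal(res@p, ct$p.value, tolerance = 1e-9)

  # null sampling: uncorrelated inputs stay near 0
  set.seed(45)
  rs <- replicate(100, abs(miAccuracyCorrelation(rnorm(50), rnorm(50))@r))
  expect_lt(median(rs), 0.2)

  expect_error(miAccuracyCorrelation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(miAccuracyCorrelation(1:2, 1:2), "length >= 3")
})

test_that("pairwise Welch tests behave at the degenerate corners", {
  same <- miDimensionTtests(list(channel = c(0, 0, 0), trial = c(0, 0, 0)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(46)
  sep <- miDimensionTtests(list(channel = rnorm(3, 0, 1e-4),
                                trial = rnorm(3, 1, 1e-4)))
  expect_lt(sep$p, 0.01)

  a <- c(0.1, 0.4, 0.3); b <- c(0.9, 1.2, 0.8)
  ab <- miDimensionTtests(list(x = a, y = b))
  ba <- miDimensionTtests(list(x = b, y = a))
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, unname(t.test(a, b)$statistic))

  expect_error(miDimensionTtests(list(a = 1, b = c(1, 2))), "at least 2")
})
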