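test_that("standardizer is fitted on training rows only", {
  set.seed(1)
  X <- matrix(rnorm(200 * 6, mean = 3, sd = 2), 200, 6)
  f <- fitStandardizer(X)
  Z <- applyStandardizer(f, X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)

  # constant feature maps to zero everywhere, with a warning at fit time
  Xc <- cbind(X, 5)
  expect_warning(fc <- fitStandardizer(Xc), "zero-variance")
  held <- cbind(matrix(rnorm(50 * 6, 3, 2), 50, 6), 9)
  Zh <- applyStandardizer(fc, held)
  expect_equal(max(abs(Zh[, 7])), 0)

  # held-out rows from the same distribution stay near zero mean
  Zo <- applyStandardizer(f, matrix(rnorm(4000 * 6, 3, 2), 4000, 6))
  se <- 1 / sqrt(4000)
  expect_true(all(abs(colMeans(Zo)) < 3 * se + 3 * 1 / sqrt(200)))

  expect_error(applyStandardizer(f, matrix(0, 3, 4)), "feature count")
})

test_that("PCA keeps the smallest component count reaching the variance threshold", {
  set.seed(2)
  # exact rank 2 embedded in 40 features
  basis <- matrix(rnorm(80), 2, 40)
  X <- matrix(rnorm(120 * 2), 120, 2) %*% basis
  expect_equal(pcaReduce(X, varThreshold = 0.99)$nComponents, 2L)

  # full threshold on full-rank data: min(n - 1, p) components
  Xf <- matrix(rnorm(30 * 8), 30, 8)
  expect_equal(pcaReduce(Xf, varThreshold = 1)$nComponents, 8L)
  Xs <- matrix(rnorm(6 * 8), 6, 8)
  expect_equal(pcaReduce(Xs, varThreshold = 1)$nComponents, 5L)

  # isotropic noise: equal eigenvalues force all 40 components at 0.99
  Xw <- matrix(rnorm(4000 * 40), 4000, 40)
  expect_equal(pcaReduce(Xw, varThreshold = 0.99)$nComponents, 40L)

  expect_error(pcaReduce(Xf, varThreshold = 0), "varThreshold")
})

test_that("PCA projection never depends on test rows", {
  set.seed(3)
  tr <- matrix(rnorm(60 * 10), 60, 10)
  te1 <- matrix(rnorm(20 * 10), 20, 10)
  te2 <- te1 + 100
  r1 <- pcaReduce(tr, te1, 0.9)
  r2 <- pcaReduce(tr, te2, 0.9)
  expect_identical(r1$rotation, r2$rotation)
  expect_identical(r1$train, r2$train)
})

test_that("BH step-up matches its definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bhAdjust(c(0.2, 0.9), 0.05), rep(FALSE, 2))
  expect_true(bhAdjust(0.05, 0.05))  # boundary is inclusive
  expect_equal(bhAdjust(numeric(0), 0.05), logical(0))
  expect_error(bhAdjust(c(0.5, 1.2), 0.05), "\\[0, 1\\]")

  set.seed(4)
  for (r in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 2)
    expect_equal(bhAdjust(p, 0.1), bruteBH(p, 0.1))
  }
})

test_that("permutation t-test selection recovers the informative channels", {
  set.seed(11)
  nTr <- 60; nCh <- 10; sf <- 100
  times <- seq(-0.2, 0.995, by = 1 / sf)
  data <- array(rnorm(nTr * nCh * length(times)),
                c(nTr, nCh, length(times)))
  labels <- rep(c(0L, 1L), each = nTr / 2)
  win <- times >= 0.2 & times <= 0.6
  for (ch in c(3, 7))
    data[labels == 1L, ch, win] <- data[labels == 1L, ch, win] + 1.5
  E <- EpochsSet(data, labels, rep(1:(nTr / 2), 2), times = times,
                 sfreq = sf, modality = "meg")
  mask <- univariateSelectChannels(E, ReducerSpec("univariate",
                                                  nPermutations = 1000L,
                                                  seed = 2))
  expect_equal(which(mask), c(3L, 7L))

  # an effect stronger than every permutation hits the add-one floor
  for (ch in c(3, 7))
    data[labels == 1L, ch, win] <- data[labels == 1L, ch, win] + 20
  E2 <- EpochsSet(data, labels, rep(1:(nTr / 2), 2), times = times,
                  sfreq = sf, modality = "meg")
  m2 <- univariateSelectChannels(E2, ReducerSpec("univariate",
                                                 nPermutations = 500L,
                                                 seed = 3))
  expect_equal(min(attr(m2, "pValues")), 1 / 501)

  # scale invariance of the t statistic: p-values unchanged
  E3 <- E
  E3@data[, 4, ] <- E3@data[, 4, ] * 10
  m3 <- univariateSelectChannels(E3, ReducerSpec("univariate",
                                                 nPermutations = 1000L,
                                                 seed = 2))
  expect_equal(attr(m3, "pValues"), attr(mask, "pValues"))
})

test_that("channel selection is calibrated under the null", {
  fp <- replicate(100, {
    d <- array(rnorm(40 * 8 * 60), c(40, 8, 60))
    E <- EpochsSet(d, rep(c(0L, 1L), each = 20), rep(1:20, 2),
                   times = seq(-0.1, 0.49, by = 0.01), sfreq = 100,
                   modality = "meg")
    suppressWarnings(mean(univariateSelectChannels(E,
      ReducerSpec("univariate", selectWindow = c(0.1, 0.4),
                  nPermutations = 300L, seed = 1))))
  })
  # BH at q = 0.05 keeps the false-selection proportion at or below q
  expect_lte(mean(fp), 0.05 + 2 * sd(fp) / sqrt(length(fp)))
})

test_that("parametric paired fallback agrees with t.test", {
  e <- whiteNoiseEpochs(nTrials = 30, nCh = 4, nT = 60, sfreq = 100,
                        tMin = -0.1, seed = 12)
  spec <- ReducerSpec("univariate", selectWindow = c(0.1, 0.4),
                      parametric = TRUE)
  m <- suppressWarnings(univariateSelectChannels(e, spec))
  idx <- which(epochTimes(e) >= 0.1 & epochTimes(e) <= 0.4)
  M <- rowMeans(epochsData(e)[, , idx], dims = 2)
  d <- M[trialLabels(e) == 1L, ][order(pairIds(e)[trialLabels(e) == 1L]), ] -
       M[trialLabels(e) == 0L, ][order(pairIds(e)[trialLabels(e) == 0L]), ]
  ref <- apply(d, 2, function(x) t.test(x)$p.value)
  expect_equal(unname(attr(m, "pValues")), unname(ref), tolerance = 1e-12)
})
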