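test_that("baseline correction subtracts the pre-stimulus mean and is idempotent", {
  e <- whiteNoiseEpochs(nTrials = 6, nCh = 3, nT = 40, sfreq = 100,
                        tMin = -0.2, seed = 2)
  # constant epoch becomes all zeros
  ec <- e
  ec@data[] <- 7.5
  expect_equal(max(abs(epochsData(baselineCorrect(ec, c(-0.2, 0))))), 0)

  b <- baselineCorrect(e, c(-0.2, 0))
  idx <- which(epochTimes(e) >= -0.2 & epochTimes(e) <= 0)
  expect_lt(max(abs(rowMeans(epochsData(b)[, , idx], dims = 2))), 1e-12)
  # post-interval samples are shifted by the pre-stimulus mean
  pre <- rowMeans(epochsData(e)[, , idx], dims = 2)
  expect_equal(epochsData(b)[, , 30], epochsData(e)[, , 30] - pre)
  # idempotent
  expect_equal(epochsData(baselineCorrect(b, c(-0.2, 0))), epochsData(b))
  expect_error(baselineCorrect(e, c(5, 6)), "no samples")
})

test_that("z-score flagging rejects exactly the trials above threshold", {
  e <- whiteNoiseEpochs(nTrials = 20, nCh = 4, nT = 50, seed = 3)
  spiky <- e
  spiky@data[7, 2, 25] <- 50
  res <- flagBadEpochs(spiky, threshold = 10)
  expect_equal(res$rejected, 7L)
  expect_equal(nTrials(res$kept), 19L)
  expect_equal(pairIds(res$kept), pairIds(e)[-7])

  expect_equal(length(flagBadEpochs(e, Inf)$rejected), 0L)

  # brute-force the per-trial max |z| and set the threshold just below it
  d <- epochsData(e)
  z <- d
  for (ch in 1:4) {
    v <- as.vector(d[, ch, ])
    z[, ch, ] <- (d[, ch, ] - mean(v)) / sd(v)
  }
  perTrial <- apply(abs(z), 1, max)
  res2 <- flagBadEpochs(e, threshold = max(perTrial) - 1e-9)
  expect_equal(res2$rejected, which.max(perTrial))
  expect_equal(length(res2$rejected), 1L)

  expect_error(flagBadEpochs(e, threshold = 1e-6), "raise the threshold")
})

test_that("resampling decimates with anti-alias filtering", {
  spec <- SimulationSpec(nSubjects = 1L, nTrials = 4L, nChannelsMeg = 2L,
                         nChannelsEeg = 2L)
  e <- generateSubject(spec, 1, modalities = "meg")$meg
  r <- resampleEpochs(e, 200)
  expect_equal(nTimepoints(r), 240L)
  expect_equal(samplingRate(r), 200)
  expect_equal(epochTimes(r)[1], epochTimes(e)[1])
  # identity path
  expect_identical(epochsData(resampleEpochs(e, 1000)), epochsData(e))
  expect_error(resampleEpochs(e, -5), "positive")
  expect_error(resampleEpochs(e, 2000), "exceed")

  # tones: passband amplitude preserved, stopband rejected
  times <- seq(0, 1.2 - 1e-9, by = 1e-3)
  tone <- function(f) sin(2 * pi * f * times)
  mk <- function(v) EpochsSet(array(rep(v, each = 2), c(1, 2, length(v))),
                              labels = 0L, times = times, sfreq = 1000,
                              modality = "meg")
  # 1.2 s holds whole cycles of both tones, so there is no edge
  # discontinuity; RMS-based amplitude avoids sampling-phase artifacts
  rmsAmp <- function(v) sqrt(2 * mean(v^2))
  lo <- resampleEpochs(mk(tone(10)), 100)
  expect_lt(abs(rmsAmp(epochsData(lo)[1, 1, ]) - 1), 0.01)
  hi <- resampleEpochs(mk(tone(450)), 100)
  expect_lt(rmsAmp(epochsData(hi)[1, 1, ]), 0.05)
})

test_that("sliding windows tile the epoch as documented", {
  e <- whiteNoiseEpochs(nTrials = 4, nCh = 2, nT = 1200, sfreq = 1000,
                        tMin = -0.2, seed = 5)
  w <- slidingWindowAverage(e, 10, 0.6)
  expect_equal(nTimepoints(w), 199L)  # floor((1200 - 10) / 6) + 1

  const <- e
  const@data[] <- 3
  wc <- slidingWindowAverage(const, 20, 0.6)
  expect_equal(max(abs(epochsData(wc) - 3)), 0)

  w1 <- slidingWindowAverage(e, 1, 1)
  expect_equal(epochsData(w1), epochsData(e))

  # non-overlapping windows that tile exactly preserve the overall mean
  wt <- slidingWindowAverage(e, 10, 1)
  expect_equal(mean(epochsData(wt)[2, 1, ]), mean(epochsData(e)[2, 1, ]),
               tolerance = 1e-12)
  expect_error(slidingWindowAverage(e, 5000), "longer than the epoch")
})

test_that("trial averaging forms disjoint seeded groups and drops leftovers", {
  e <- whiteNoiseEpochs(nTrials = 192, nCh = 2, nT = 5, seed = 6)
  a2 <- averageTrials(e, 2, seed = 9)
  expect_equal(nTrials(a2), 96L)
  expect_equal(sum(trialLabels(a2) == 0L), 48L)
  expect_true(all(is.na(pairIds(a2))))

  # 98 trials per condition, groups of 6: 16 pseudo-trials each, 2 dropped
  e98 <- whiteNoiseEpochs(nTrials = 196, nCh = 2, nT = 5, seed = 7)
  a6 <- averageTrials(e98, 6, seed = 1)
  expect_equal(sum(trialLabels(a6) == 0L), 16L)
  expect_equal(sum(trialLabels(a6) == 1L), 16L)

  # k = 1 is the identity up to ordering
  a1 <- averageTrials(e, 1, seed = 2)
  expect_equal(sort(epochsData(a1)[, 1, 1]), sort(epochsData(e)[, 1, 1]))

  # groups are disjoint and within-condition
  g <- attr(averageTrials(e, 4, seed = 3, returnGroups = TRUE), "groups")
  allIdx <- unlist(g)
  expect_false(anyDuplicated(allIdx) > 0)
  for (grp in g) expect_equal(length(unique(trialLabels(e)[grp])), 1L)

  expect_error(averageTrials(whiteNoiseEpochs(nTrials = 4), 3), "fewer")
})

test_that("pseudo-trial variance shrinks by the group size", {
  e <- whiteNoiseEpochs(nTrials = 800, nCh = 1, nT = 4, seed = 8)
  a <- averageTrials(e, 4, seed = 1)
  expect_equal(nTrials(a), 200L)
  v <- var(as.vector(epochsData(a)))
  expect_lt(abs(v - 0.25) / 0.25, 0.10)
})

test_that("balancing downsamples the majority class only", {
  e <- whiteNoiseEpochs(nTrials = 40, nCh = 2, nT = 5, seed = 9)
  # drop 4 trials of class 1 -> counts (20, 16)
  unb <- e[-which(trialLabels(e) == 1L)[1:4]]
  bal <- balanceEpochs(unb, seed = 5)
  expect_equal(sum(trialLabels(bal) == 0L), 16L)
  expect_equal(sum(trialLabels(bal) == 1L), 16L)
  # minority trials all survive
  expect_true(all(pairIds(unb)[trialLabels(unb) == 1L] %in% pairIds(bal)))
  # already balanced: unchanged
  expect_identical(epochsData(balanceEpochs(e, seed = 1)), epochsData(e))
  # determinism
  expect_identical(trialLabels(balanceEpochs(unb, seed = 5)),
                   trialLabels(balanceEpochs(unb, seed = 5)))
  empty <- tryCatch(balanceEpochs(e[trialLabels(e) == 0L]),
                    error = function(e) "err")
  expect_equal(empty, "err")
})

test_that("collapse operators preserve channels and the label alphabet", {
  e <- whiteNoiseEpochs(nTrials = 24, nCh = 3, nT = 60, sfreq = 100,
                        tMin = -0.2, seed = 10)
  ops <- list(
    function(x) baselineCorrect(x, c(-0.2, 0)),
    function(x) resampleEpochs(x, 50),
    function(x) slidingWindowAverage(x, 20, 0.6),
    function(x) averageTrials(x, 2, seed = 1),
    function(x) balanceEpochs(x, seed = 1),
    function(x) flagBadEpochs(x, 8)$kept)
  for (op in ops) {
    out <- op(e)
    expect_equal(nChannels(out), 3L)
    expect_true(all(trialLabels(out) %in% c(0L, 1L)))
  }
})
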