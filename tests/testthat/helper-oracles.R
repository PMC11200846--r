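# Shared fixtures and independent oracles used across test files.

# White-noise epochs with a paired two-condition layout.
whiteNoiseEpochs <- function(nTrials = 20, nCh = 4, nT = 30, sfreq = 100,
                             tMin = -0.1, seed = 1, modality = "meg") {
  set.seed(seed)
  EpochsSet(array(rnorm(nTrials * nCh * nT), c(nTrials, nCh, nT)),
            labels = rep(c(0L, 1L), each = nTrials / 2),
            pairIds = rep(seq_len(nTrials / 2), 2),
            sfreq = sfreq, tMin = tMin, modality = modality,
            subjectId = "fix")
}

# Brute-force exact signed-rank tail probability by enumerating all 2^n
# sign assignments (n <= ~12). Independent of the package implementation
# except for the shared mid-rank convention.
bruteWilcoxonP <- function(diffs, alternative = "greater") {
  d <- diffs[diffs != 0]
  if (length(d) == 0) return(1)
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  wObs <- sum(r2[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% r2)
  if (alternative == "greater") mean(wAll >= wObs) else mean(wAll <= wObs)
}

# Brute-force BH step-up by its definition: find the largest i with
# p_(i) <= (i/m) q, reject everything at or below that sorted p-value.
bruteBH <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}
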