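---
title: "Time-resolved decoding of evoked M/EEG epochs: models and methods"
author: "evokedMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of evoked M/EEG epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokedMVPA)
```

## The problem

Multivariate pattern analysis (MVPA) of evoked magnetoencephalography and
electroencephalography asks, at each peristimulus timepoint, whether a
classifier can tell two experimental conditions apart from the
multichannel sensor pattern. The output is a *decoding curve*: accuracy
as a function of time, one classifier per timepoint. Applied to a
semantic-congruity paradigm, the curve rises where condition information
is present in the signal — classically around the N400(m) component near
400 ms post-stimulus.

This package implements that workflow end to end for epoched data:

1. **Conditioning / SNR collapse** — baseline correction, z-score epoch
   flagging, anti-alias resampling, sliding-window averaging,
   pseudo-trial (within-condition) averaging, class balancing.
2. **Dimensionality reduction** — per-fold standardization and
   variance-threshold PCA, or univariate channel selection by a paired
   permutation *t*-test with Benjamini–Hochberg control.
3. **Decoding** — per-timepoint stratified K-fold cross-validation with
   LDA, ridge, or a sigmoid-kernel SVM, plus MEG–EEG feature fusion.
4. **Group inference** — per-timepoint exact one-sided Wilcoxon
   signed-rank tests of subject accuracies against chance.
5. **Information loss** — a Gaussian-mixture / Monte-Carlo /
   k-nearest-neighbour mutual-information estimate of how much of the
   original signal a reduction operation retains.

Because real recordings of this kind are typically not shareable, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis assumes; every calibration claim the package makes
is demonstrated on that generator.

## The synthetic generator

`SimulationSpec()` describes a cohort; `generateSubject()` /
`generateCohort()` build `EpochsSet` objects. The generative model for a
trial of subject $s$, channel $c$, time $t$ is

$$x_{c}(t) = \sum_k a_k w^{(k)}_c h_k(t) \;+\; y \cdot \alpha_s A\, w_c\,
h\!\left(t; \mu_s, \sigma\right) \;+\; \varepsilon_c(t),$$

where $h(\cdot)$ are Hanning-tapered bumps (smooth, compactly supported),
$y \in \{0,1\}$ is the condition label, $w$ are fixed random spatial
patterns, and $\varepsilon$ is AR(1)-colored noise with
squared-exponential spatial correlation over a 1-d channel ordering plus
white sensor noise. Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `nSubjects` | 6 | small-cohort regime the exact group test targets |
| `nTrials` | 196 | paired design: 98 stimuli, each once per condition |
| channels | 40 MEG / 64 EEG | typical wearable-magnetometer and cap sizes |
| `sfreq`, window | 1000 Hz, −0.2..1.0 s | 1200-sample epochs |
| `effectLatency`, `effectWidth` | 0.40 s, 0.15 s | N400m-like difference component |
| `effectAmplitude` | 0.12 | calibrated once so the default pipeline peaks near 0.65, the realistic single-trial range; 0 gives an exact null |
| `ar1Coefficient` | 0.95 | low-passed background with ~20 ms time constant |
| `spatialCorrelationLength` | 5 channels | makes PCA genuinely useful |
| `sensorNoiseSd` | 0.3 | white instrument-noise floor |
| `amplitudeSd`, `latencyJitterSd` | 0.2, 20 ms | between-subject variability |
| `megScale`, `eegScale` | 1e−13, 1e−6 | tesla-like and volt-like units |

Random streams are split per (seed, subject, role), so extending a cohort
never perturbs earlier subjects, and each modality can be generated alone
bit-identically. Spatial patterns derive from the seed and modality only:
they are properties of the simulated "head", not of a subject.

**What the generator does not emulate:** realistic sensor geometry and
forward fields, artifacts (blinks, cardiac), non-stationary noise,
overlapping cascades of late components, and condition-correlated noise.
Passing calibration tests on this generator therefore shows that the
*pipeline machinery* is correct and calibrated — not that any particular
real dataset will decode.

## Conditioning choices

* **Resampling** uses a zero-phase frequency-domain low-pass
  (raised-cosine transition from 0.8× to 1.0× the new Nyquist) followed by
  integer-factor decimation. Zero-phase filtering preserves component
  latencies, which are an analysis endpoint. The frequency-domain
  implementation treats the epoch circularly; epochs with strong edge
  discontinuities should be baseline-corrected first (the default
  pipeline does).
* **Sliding windows** are anchored at the epoch start with step
  `round(0.6 × L)` samples and output timestamps at window centers, which
  minimizes latency bias. Only windows wholly inside the epoch are kept.
* **Pseudo-trial averaging** partitions each condition at random into
  disjoint groups of exactly `k`; leftovers are dropped rather than merged
  so pseudo-trial noise variance stays homogeneous. Averaging happens
  before CV splitting — pseudo-trials are the CV unit — which cannot leak
  labels because it is within-condition. Pair ids are invalidated on
  output.
* **z-score flagging** standardizes each channel over all trials and
  timepoints and summarizes a trial by its maximum |z|. The threshold is a
  knob with no default: it is data-dependent in practice, and the
  synthetic data contain no artifacts to flag.
* The composition order used by `decodeTimecourse()` is explicit:
  balance → baseline/resample/window → average-trials → decode.

## Dimensionality reduction

Standardization and PCA are fitted **within each CV fold on training rows
only** and applied to both sides; perturbing test rows provably leaves
the projection bit-identical. The component count is the smallest one
whose cumulative explained variance reaches the threshold (default 99%).

Channel selection scores each channel by the *t*-statistic of the
condition difference of its window-mean amplitude over 200–600 ms, paired
across stimulus ids. The null is built by within-pair sign flipping
(label shuffling when pairing is unavailable), p-values use the add-one
rule $(1 + \#\{|t_\pi| \ge |t_{obs}|\})/(1+B)$ with $B = 1000$ by
default, and the BH step-up at $q = 0.05$ runs across channels. A
parametric paired-*t* fallback is available (`parametric = TRUE`). We
kept the permutation + BH combination as the single canonical selector
because it is the strictest internally consistent reading of the usual
practice; one test per channel (window mean) avoids pooling decisions
over timepoints. An empty selection falls back to all channels with a
warning. Selection is computed once per subject on the full epoch set —
the standard practice this mirrors — so its output should be read as
descriptive feature selection, not as a fully nested procedure.

## Decoding

Classifiers are deliberately simple:

* **LDA** — singular-value solver, no shrinkage, tolerance $10^{-4}$
  (via MASS).
* **Ridge as a classifier** — closed-form ridge regression on ±1 targets
  with $\alpha = 1$ and an unpenalized intercept; prediction is the sign
  of the output, with ties broken toward class 0. The closed form is the
  exact minimizer any iterative solver approximates.
* **Sigmoid-kernel SVM** — tolerance $10^{-4}$, shrinking on,
  $\gamma = 1/(d \cdot \mathrm{Var}(X))$, `coef0 = 0` (via e1071). The
  kernel coefficients are recorded in the config because the sigmoid
  kernel has no separability guarantee.

Stratified K-fold partitions use a single seeded shuffle per
(subject, config); every fold's class counts differ by at most one. The
partition is built once and reused across timepoints, so curves are
deterministic given the config seed. Chance level is 0.5 for balanced
binary labels.

**Fusion** matches trials across modalities by (pair id, label), balances
the matched set, scales every channel to unit variance over the whole
epoch set, and concatenates the channel axes.

## Group inference

With six subjects, large-sample approximations of the signed-rank
distribution are invalid, so `wilcoxonSignedRankExact()` evaluates the
exact null by a generating-function convolution over the (doubled,
integer) mid-ranks — identical to enumerating all $2^n$ sign patterns,
exact under ties, with zeros dropped by the standard convention. Above
$n = 25$ it switches to a continuity-corrected normal approximation with
tie-corrected variance. The smallest attainable one-sided p at $n = 6$ is
$1/64$; the attainable level closest to 0.05 is $3/64 \approx 0.0469$, so
the per-timepoint test is slightly conservative.

**No correction is applied across timepoints.** Significance discs on
decoding curves are per-timepoint statements; false-discovery control is
reserved for channel selection. Isolated significant points, especially
late in the epoch, should be interpreted with care. The difference-curve
test against zero is one-sided (greater), matching the directional
question "is modality A better than B here?".

## The mutual-information procedure

To quantify what a reduction operation discards,
`buildReductionPairs()` pairs each (trial, timepoint) observation's full
channel vector with the representation the operation assigns to that same
observation — the reduced channel vector, the pseudo-trial vector of the
trial's group, or the vector at the containing decimated
timepoint/window. This pairing makes "the MI between the data before and
after reduction" well defined; `estimateMi()` then:

1. fits Gaussian mixtures (full covariance, AIC-selected component count
   over 1..10) to the benchmark rows, the operated rows, and their joint
   concatenation;
2. draws Monte-Carlo samples from the joint fit;
3. computes the Kraskov (KSG) k-nearest-neighbour estimate
   ($k = 3$) on the sampled pairs — the reported value — and a
   density-ratio estimate $\langle \log p_J - \log p_X - \log p_Y
   \rangle$ from the fitted densities as a diagnostic;
4. averages over repeats (only the sampling varies across repeats; the
   mixture fits are deterministic given data and seed) and clips the
   result at 0.

Defaults: 10 000 MC samples, 10 repeats, observations capped at 20 000
rows. MI is reported in nats. Degenerate (zero-variance) operated data
yield MI = 0 with a warning. Mixture fitting is initialized from a seeded
1000-row subset, and fits fall back to diagonal covariances when
observations are scarcer than dimensions. The estimator is validated
against the closed form
$I = \tfrac12(\log\det\Sigma_X + \log\det\Sigma_Y - \log\det\Sigma_{XY})$
for Gaussian inputs; at $\rho = 0.9$ the KSG estimator carries a small
negative bias (≈0.01–0.04 nats at these sample sizes), well inside the
tolerances the tests assert.

Downstream, `miAccuracyCorrelation()` relates per-subject MI to the
difference in peak group-mean accuracy with/without the operation
(Pearson, p from $t_{n-2}$), and `miDimensionTtests()` compares MI across
the channel/trial/temporal reduction dimensions with pairwise Welch
tests.

## Calibration results and the problem sizes behind them

The test suite and `scripts/acceptance.R` recompute two headline
calibrations from scratch; all sizes below are the package's chosen
desk-scale study conditions:

* **Chance calibration** — 20 replicate null subjects (zero effect, 192
  balanced trials, 40 channels, 1000 Hz resampled to 200 Hz) decoded with
  the default pipeline; the accuracy averaged over timepoints and
  replicates must lie within 0.5 ± 0.02.
* **Type-I calibration** — 200 null cohorts of 6 subjects on a
  50-timepoint grid (50 Hz native sampling over −0.2..0.8 s, 64 trials,
  12 channels, 5-fold CV — one of the package's standard fold counts —
  and no reduction, since the Wilcoxon calibration does not depend on
  those choices); the fraction of significant timepoints must not exceed
  the nominal 0.05 beyond binomial error. The exact test's attainable
  level is 3/64 ≈ 0.0469, so the empirical rate typically lands just
  under 0.05.

Further checks: the exact Wilcoxon is bit-identical to brute-force
$2^n$ enumeration for $n \le 10$; BH matches its step-up definition
exhaustively for $m \le 10$; full-variance PCA leaves LDA decoding
invariant to within $10^{-9}$ (LDA is invariant under invertible linear
maps); and on high-SNR cohorts the replicate-averaged decoding curve
peaks within 400 ± 30 ms with peak accuracy strictly increasing in the
generative effect amplitude.

## Known limitations

* The per-timepoint group test is uncorrected over time by design; users
  who need familywise control over the curve should add cluster-based or
  maximum-statistic corrections externally.
* The sigmoid-kernel SVM can underperform even on separable data; it is
  included as the nonlinear comparison point, not as a recommendation.
* KSG MI estimates inherit a sample-size-dependent bias; comparisons
  across operations should hold the observation count fixed (the
  observation cap does this).
* The raw+JSON epochs layout is deliberately minimal; it stores no
  sensor positions or filter provenance.
* Univariate channel selection is per-subject and pre-CV; its accuracy
  curves are therefore mildly optimistic relative to fully nested
  selection.
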