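Package: evokedMVPA
Title: Time-Resolved Multivariate Pattern Analysis for Evoked M/EEG Epochs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for time-resolved decoding of evoked magnetoencephalography
    and electroencephalography epochs. Provides an S4 container for epoched
    multichannel recordings with condition labels and paired-trial identifiers,
    a synthetic evoked-data generator with colored spatially correlated noise,
    signal-to-noise collapse operators (baseline correction, z-score epoch
    flagging, anti-alias resampling, sliding-window averaging, pseudo-trial
    averaging, class balancing), fold-wise standardization and dimensionality
    reduction (variance-threshold PCA, permutation t-test channel selection
    with Benjamini-Hochberg control), per-timepoint stratified cross-validated
    classification (LDA, ridge, sigmoid-kernel SVM) with multimodal fusion,
    exact small-sample Wilcoxon signed-rank group inference on decoding
    curves, and a Gaussian-mixture / Monte-Carlo / k-nearest-neighbour mutual
    information procedure for quantifying the information retained after a
    reduction operation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    e1071,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate.R'
    'collapse.R'
    'dimreduction.R'
    'decoding.R'
    'groupstats.R'
    'infoloss.R'
    'io.R'
    'grid.R'
    'plot.R'
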