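Package: emgsort
Title: Simulation, Sorting Primitives, and Ground-Truth Evaluation for
    Multichannel Motor-Unit Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for intramuscular electromyography (EMG) spike
    sorting research. Simulates multichannel motor-unit action potential
    (MUAP) recordings with known ground truth using a recruitment model
    with exponential activation thresholds, sigmoid-binomial firing, and
    a spike-history kernel; morphs template waveforms with per-spike
    gain noise and fits per-channel additive noise to target median
    absolute deviation (MAD) levels with an Adam optimizer. Provides
    recording-side preprocessing (band-pass and notch filtering, bad
    channel rejection, whitening, cross-channel delay estimation and
    removal), a template-initialization chain (multi-threshold
    extraction of time-isolated waveforms, density-based outlier
    rejection, principal-component temporal bases, K-means simple
    templates, convolutional detection), a three-stage ground-truth
    evaluator yielding precision, recall, and accuracy per unit with
    overlap-restricted variants, and a composite sort-quality score for
    ranking parameter sweeps without ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
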