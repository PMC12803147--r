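---
title: "Simulating and evaluating motor-unit spike sorting with emgsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating motor-unit spike sorting with emgsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsort)
```

## The problem

Intramuscular multielectrode arrays record the summed extracellular
signatures of motor-unit action potentials (MUAPs). Sorting these
recordings into per-unit spike trains is harder than cortical spike
sorting for three reasons: MUAPs propagate along muscle fibres, so the
same event appears on different channels with conduction delays of up to
a couple of milliseconds; MUAP waveforms are more complex (multiphasic)
than neuronal action potentials; and motor units are recruited
cumulatively, so at high drive many units fire together and their
waveforms superpose. `emgsort` packages the computational machinery
needed to study this problem end to end: a generative simulator with
exact ground truth, the recording-side preprocessing (including
cross-channel delay removal), a template-initialization chain for
detection, a ground-truth evaluator, and a composite quality score for
ranking sorting runs when no ground truth exists.

## The generative model

A **template basis** factorizes each unit's multichannel waveform into a
shared orthonormal temporal basis `W` (`n_pcs x nt`) and per-unit
channel weights `U0` (`n_channels x n_pcs`). The noiseless template of
unit *i* is `b * t(w_inv %*% (U0_i %*% W))`, where `w_inv` undoes any
channel whitening used when the basis was learned and `b` converts bits
to voltage. Bases can be learned from previously sorted data and saved
to the package's container format; `make_synthetic_basis()` builds one
from scratch by composing each unit's dominant-channel waveform from 2-3
Gaussian-windowed sinusoids (which guarantees multiphasic shapes),
shifting each channel by a random conduction delay up to `max_delay`
samples, decaying amplitude exponentially with channel distance from a
random dominant channel, and then deriving `W`/`U0` by SVD so the basis
is exactly self-consistent. No published value exists for `b`, so it is
treated as a free scale with default 1.

**Spike times** come from a recruitment model. Per-unit activation
thresholds are drawn as `theta1 * Exp(1) + theta2` (the exponential rate
is fixed at 1); given a drive (force) signal `F`, a unit is eligible to
fire at sample `t` only while `F[t]` exceeds its time-varying threshold
trace, and fires with probability `sigmoid(F[t] - threshold)`. After a
spike, a history kernel is added to that unit's threshold trace:
a rectangular plateau over the absolute refractory span followed by an
exponential decay, truncated at 1% of its height. The plateau height
defaults to `10 * (max(F) - min(thresholds))`, which makes the
refractory period absolute for any drive the pool can see; the decay
time constant (default 20 ms) is what actually caps the attainable
firing rate. The kernel's functional form is a package choice — only its
effects (no refractory violations, controlled maximum rate) are
prescribed — and both properties are tested. The built-in drive
generator (`make_force_signal()`) produces periodic raised-cosine bursts
plus rectified low-pass-filtered noise, emulating the envelope of
locomotor step cycles; any non-negative array can be supplied instead.

**Waveform variability.** Each spike instance draws an elementwise
Gaussian gain matrix `G ~ N(1, 0.2)` on the channel weights, giving
`M = b * t(w_inv %*% ((U0_i * G) %*% W))`. Because the morph is linear
in `G`, the expected morphed waveform equals the template — a property
the tests verify by Monte Carlo. Each waveform is windowed by a
zero-padded Tukey window (taper 0.25, central width `0.9 * nt`, exact
zeros over `0.05 * nt` per side) so spikes contribute exactly zero at
their window edges, and added into the data matrix at its spike time;
overlapping spikes sum, and spikes at the recording edge are truncated
rather than dropped so spike-count bookkeeping stays exact. Gains are
keyed by spike identity (unit, sample), which makes superposition
additive across disjoint spike trains and independent of spike order.

**Noise matching.** Channel noise levels are summarized by the
standardized MAD, `median(|x - median(x)|) / 0.6745` (the 0.6745 factor
makes this a standard-deviation estimate for Gaussian data), evaluated
on a chunked subset of the recording — 20 evenly spaced 1-s chunks by
default; the chunk geometry is a package choice, and channel medians are
taken on the same subset for consistency. `fit_noise_levels()` learns
one additive Gaussian noise SD per channel by Adam (learning rate 1,
conventional moments 0.9/0.999, cap 3000 iterations) on the mean squared
error between current and target MADs, redrawing the noise at every
iteration and stopping when all channels are within 1% relative of
target. Three numerical choices matter here. First, the gradient through
the MAD is the same subgradient automatic differentiation would produce:
the derivative flows through the order statistics that attain the two
medians. Second, the learned sigmas are initialized at the targets —
at zero, on sparse spike data, the MAD subgradient vanishes and learning
cannot start. Third, the full-length noise realization is drawn each
iteration and the chunked MADs are computed on that same realization, so
the augmented recording the function returns is exactly the realization
that satisfied the stop rule, and an independent recomputation of the
chunked MADs on it reproduces the converged values.

## Preprocessing

Filtering uses a zero-phase 4th-order Butterworth band-pass (default
250-5000 Hz) and a zero-phase 2nd-order IIR notch (Q = 30, default 60 Hz,
configurable to 50 Hz); none of these orders is externally prescribed,
so conventional defaults are used and recorded here. Bad channels are
flagged when their robust deviation statistic exceeds `k` times the
cross-channel median (`"mad5"` by default; `std` variants use the plain
standard deviation). Whitening is symmetric (ZCA) with an optional local
variant that estimates each channel's whitening row from its
`whitening_range` nearest channels; the inverse is returned so simulated
data can be un-whitened. The channel map is a dense 1-D line with 2 um
spacing.

Cross-channel delay estimation computes Pearson correlations between
every channel pair at every integer lag within +/-2 ms (+/-60 samples at
30 kHz). Pearson correlation is chosen because the criterion is stated
only as "correlation" and the bounded values make rows comparable. The
best shift per pair is the argmax over lags, with ties broken toward the
smaller `|lag|` and then toward the negative lag; the reference channel
is the row whose best correlations sum highest (ties to the lowest
index). Whether per-row correlations should be normalized before summing
is not externally specified; the per-pair maxima are summed directly.
Applying a plan rolls each channel by its shift and zero-fills the
vacated edge samples. Estimation is exact on planted integer shifts and
agrees with exhaustive search on small instances, both tested.

## Template initialization

Detection thresholds (default 6, 9, 12, 15, in units of variance on
whitened data) each contribute threshold-crossing events: local maxima
of `|x|` with non-maximum suppression over +/-0.25 ms, so the several
lobes of one multiphasic waveform collapse to a single event while
distinct spikes 0.5 ms apart remain separate. Events with any other
event within +/-1 ms on the same or the 6 neighbouring channels on
either side are discarded (the time-isolation criterion); survivors are
aggregated across thresholds, removing exact duplicates and collapsing
near-duplicates within +/-0.2 ms to the largest-amplitude instance. Only
every `nskip`-th batch (default 2) of `batch_size` samples is scanned.
Waveforms are single-channel `nt`-sample snippets with the peak at
sample `floor(nt/3)` — the same one-third convention used when placing
simulated spikes.

Outlier rejection runs HDBSCAN on the raw snippet vectors (Euclidean
distance in the full `nt`-dimensional space, minimum cluster size 20)
and drops points labelled noise. No HDBSCAN implementation ships with
this R environment, so the package implements the algorithm itself:
core distances at `min_samples` neighbours, the mutual-reachability
transform, a single-linkage hierarchy, the condensed tree at
`min_cluster_size`, and excess-of-mass (stability) cluster selection,
with the hierarchy root eligible for selection so a homogeneous set is
not rejected wholesale. Temporal components are the top `n_pcs = 9`
uncentred principal axes of the waveform matrix; simple templates are
K-means centres (`k = 9`, k-means++ seeding, 10 restarts, fixed seed),
peak-normalized. The reference detector replicates each template across
channels with a Gaussian spatial envelope centred on every channel at
sizes 1-5 times `min_template_size` (10 um) — the Gaussian SD is set
equal to the size in um, a package choice since the decay constant is
not printed — and keeps unit-norm-kernel correlation scores above
`Th_universal = 9` that are local maxima over +/- half a window and the
10 nearest channels. This detector exists to exercise the evaluator;
the full learned-template matching and clustering tree of a production
sorter are intentionally out of scope.

## Ground-truth evaluation

Evaluation proceeds in three stages of increasing time resolution.
Stage 1 bins both spike sets at 10 ms and pairs sorted clusters to truth
units greedily, in descending order of a binned accuracy (per-bin
matched count `min(truth, sort)`; accuracy = match / (truth + sort -
match)), without replacement; the binned form of the accuracy is
implicit in the original description and this is the natural reading.
Stage 2 bins each matched pair at 0.1 ms and evaluates exactly 41
shifted copies of the sorted train (+/-20 bins), keeping the shift with
the highest Pearson correlation (ties toward zero shift, then negative).
Stage 3 applies the best shift to the actual spike times — quantized
only by the 0.1 ms bin, not re-binned — and matches each truth spike to
at most one sorted spike within +/-1 ms; when several qualify only the
closest is a true positive and the rest stay available (ultimately false
positives), and cross-truth contention is resolved greedily by ascending
`|dt|`. Precision, recall, and accuracy follow the count identities
`P = N_match/N_sort`, `R = N_match/N_truth`,
`A = N_match/(N_truth + N_sort - N_match)`, with `0/0 = 0`.

One caveat is worth knowing: when sorted spike times are jittered almost
uniformly at nearly the matching tolerance, the stage-2 correlation
profile is a plateau rather than a peak, and the argmax can land
anywhere on it; with concentrated jitter (as real sorters produce, since
they place spikes at a consistent waveform phase) the peak is sharp and
alignment is exact. The evaluator self-tests in the suite therefore use
0.3 ms jitter dispersion.

The overlap-restricted variant keeps each truth spike with at least one
*different-unit* spike within half the template window (1 ms rat-like,
2 ms monkey-like) — same-unit neighbours cannot occur at that distance
because refractory violations are excluded by construction — and
restricts the sorted side to spikes attributable to that subset within
the tolerance. `error_rate_reduction(e_new, e_ref) = 100 * (1 -
e_new/e_ref)` and `summarize_sweep()` (per-run unit means, then
median/mean/SD across runs) round out the reporting.

## Composite quality scores

Without ground truth, each cluster receives four component scores in
[0, 1], multiplied into a composite so a single error type annihilates
the cluster's score; the overall sort score is the mean composite across
clusters:

* **Type I** (false positives): `1 - R_C`, where `R_C` is the
  refractory-violation contamination estimate with a 1 ms refractory
  period. The estimator models the cluster as a refractory unit plus an
  independent Poisson contaminant of fraction `C`; counting spike pairs
  with `|dt|` in the (censored, refractory] interval gives
  `n_v = N^2 (t_r - t_c)(2C - C^2)/T`, inverted as
  `C = 1 - sqrt(1 - n_v T / (N^2 (t_r - t_c)))` and clamped to [0, 1].
  The exact estimator variant is a package decision (the original
  delegates to a metrics library); it is validated by recovering a 20%
  planted Poisson contamination to within +/-0.07 over 50 seeds.
* **Type II** (false negatives): presence ratio (fraction of 20 s bins
  with more than 0.5x the mean count) times one minus the amplitude
  cutoff (estimated missing fraction from a 32-bin amplitude histogram
  smoothed with a 1-bin Gaussian kernel, under a symmetry assumption;
  a peak at the histogram edge returns the worst case 0.5).
* **Firing-rate validity**: `1/(1+e^(rate-200)) * 1/(1+e^(range-200))`,
  logistic penalties centred at 200 Hz on the mean rate and on the
  95th-minus-5th percentile of 0.5 s-binned rates.
* **SNR**: `1 - 1/(1+e^(SNR-4))`, a sigmoid with midpoint 0.5 at SNR 4;
  cluster SNR is the mean-waveform peak over the robust (MAD-based)
  channel noise SD, maximized over channels.

On simulated sorts with graded degradation the overall composite score
correlates positively (Spearman) with mean ground-truth accuracy, which
is the property that makes it useful for ranking parameter sweeps;
`rank_runs()` orders run folders by the score embedded in their names.

## What the simulator does and does not capture

The generator reproduces the features that make MUAP sorting hard:
multiphasic shapes, cross-channel conduction delays, amplitude decay
across channels, per-spike shape variability, cumulative recruitment
with realistic refractoriness, superposition at high drive, and
channel-specific Gaussian noise at calibrated levels. It does not model
electrode-geometry volume conduction, non-Gaussian or line noise,
electrode drift, or slow waveform nonstationarity, and its drive signal
is a stylized locomotor envelope rather than recorded kinematics.
Passing tests therefore demonstrate correctness of the algorithms under
these controlled conditions, not sorting performance on real recordings.

## Problem sizes and reproducibility

The test suite and the acceptance script run the reference conditions at
desk scale: the rat-like geometry (10 units, 8 channels, 61-sample
windows at 30 kHz) over 60 s for the noise-fit and ranking checks, and
smaller planted-signal instances for the exact-recovery checks.
Monte-Carlo checks use 10^4 morph draws, 10^5 threshold draws, and 50
seeds for the contamination oracle. Every source of randomness flows
from one root seed through named substreams (so, e.g., changing the
number of units does not perturb the force generator), and identical
seeds reproduce recordings bit for bit.
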