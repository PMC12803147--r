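# Ground-truth-free sort quality: four component scores per cluster and
# their product (the composite score), averaged across clusters to rank
# parameter-sweep runs.

#' Refractory-violation contamination estimate
#'
#' Models the cluster as a mixture of a perfectly refractory unit and an
#' independent Poisson contaminant of fraction `C`. The expected number
#' of spike pairs violating the refractory period then satisfies
#' `n_v = N^2 (t_r - t_c) (2C - C^2) / T`, which inverts to
#' `C = 1 - sqrt(1 - n_v T / (N^2 (t_r - t_c)))`; the estimate is clamped
#' to `[0, 1]` (1 when the violation count exceeds what full
#' contamination explains).
#'
#' @param times_s Sorted spike times in seconds.
#' @param duration_s Recording length in seconds.
#' @param refractory_ms Refractory period `t_r` (1 ms).
#' @param censored_ms Censored period `t_c` below which violating pairs
#'   are ignored (detector dead time).
#' @return Estimated contamination fraction in `[0, 1]`.
#' @export
llobet_contamination <- function(times_s, duration_s, refractory_ms = 1,
                                 censored_ms = 0) {
  n <- length(times_s)
  if (n < 2L) return(0)
  t_r <- refractory_ms / 1000
  t_c <- censored_ms / 1000
  x <- sort(times_s)
  # violating pairs with |dt| in (t_c, t_r]
  n_v <- sum(findInterval(x + t_r, x) - findInterval(x + t_c, x))
  arg <- 1 - n_v * duration_s / (n^2 * (t_r - t_c))
  if (arg < 0) return(1)
  min(max(1 - sqrt(arg), 0), 1)
}

#' Type-I (false-positive) score
#'
#' `S_T1 = 1 - R_C`, with `R_C` the refractory-violation contamination
#' estimate at a 1 ms refractory period. Clusters with fewer than 2
#' spikes score 1 and carry a `low_count` attribute.
#'
#' @param times_s Spike times in seconds.
#' @param duration_s Recording length in seconds.
#' @param refractory_ms Refractory period in ms.
#' @param censored_ms Censored period in ms.
#' @return Score in `[0, 1]`.
#' @export
type1_score <- function(times_s, duration_s, refractory_ms = 1,
                        censored_ms = 0) {
  if (duration_s <= 0) stop("duration must be positive")
  if (length(times_s) < 2L) {
    return(structure(1, low_count = TRUE))
  }
  1 - llobet_contamination(times_s, duration_s, refractory_ms, censored_ms)
}

#' Presence ratio
#'
#' Fraction of coarse time bins (20 s) whose spike count exceeds
#' `mean_fr_ratio` times the mean count per bin.
#'
#' @param times_s Spike times in seconds.
#' @param duration_s Recording length in seconds.
#' @param bin_s Bin width in seconds.
#' @param mean_fr_ratio Threshold as a fraction of the mean bin count.
#' @return Fraction in `[0, 1]`.
#' @export
presence_ratio <- function(times_s, duration_s, bin_s = 20,
                           mean_fr_ratio = 0.5) {
  n_bins <- max(1L, floor(duration_s / bin_s))
  if (length(times_s) == 0L) return(0)
  counts <- tabulate(pmin(floor(times_s / (duration_s / n_bins)) + 1L, n_bins),
                     nbins = n_bins)
  mean(counts > mean_fr_ratio * mean(counts))
}

#' Amplitude-cutoff estimate of missed spikes
#'
#' Assumes a valid cluster has a symmetric (Gaussian) amplitude
#' distribution: builds a 32-bin histogram, smooths it with a 1-bin
#' Gaussian kernel, and estimates the missing fraction as the tail mass
#' beyond the point where the density returns to its low-amplitude-edge
#' level, clamped to `[0, 0.5]`. A peak at the histogram edge means the
#' distribution is visibly truncated and returns the worst case 0.5.
#'
#' @param amplitudes Per-spike amplitudes.
#' @param n_bins Histogram bins (32).
#' @param smooth_bins Gaussian smoothing SD in bins.
#' @return Estimated missing fraction in `[0, 0.5]`.
#' @export
amplitude_cutoff <- function(amplitudes, n_bins = 32, smooth_bins = 1) {
  if (length(amplitudes) < 2L) return(0.5)
  h <- graphics::hist(amplitudes, breaks = seq(min(amplitudes),
                                               max(amplitudes),
                                               length.out = n_bins + 1L),
                      plot = FALSE)$counts
  kern_x <- -(3 * smooth_bins):(3 * smooth_bins)
  kern <- stats::dnorm(kern_x, sd = smooth_bins)
  kern <- kern / sum(kern)
  pdf <- as.numeric(stats::filter(c(rep(h[1], 3 * smooth_bins), h,
                                    rep(h[n_bins], 3 * smooth_bins)),
                                  kern, sides = 2))
  pdf <- pdf[(3 * smooth_bins + 1):(3 * smooth_bins + n_bins)]
  peak <- which.max(pdf)
  if (peak == 1L) return(0.5)
  tail_region <- peak:n_bins
  G <- tail_region[which.min(abs(pdf[tail_region] - pdf[1]))]
  min(sum(pdf[G:n_bins]) / sum(pdf), 0.5)
}

#' Type-II (false-negative) score
#'
#' `S_T2 = R_P * (1 - A_C)`: presence ratio (20 s bins, 0.5 mean-rate
#' threshold) times one minus the amplitude-cutoff missing fraction
#' (32 bins). Zero spikes score 0.
#'
#' @param times_s Spike times in seconds.
#' @param amplitudes Per-spike amplitudes aligned with `times_s`.
#' @param duration_s Recording length in seconds.
#' @param bin_s,mean_fr_ratio Presence-ratio parameters.
#' @param n_hist_bins Amplitude-cutoff histogram bins.
#' @return Score in `[0, 1]`.
#' @export
type2_score <- function(times_s, amplitudes, duration_s, bin_s = 20,
                        mean_fr_ratio = 0.5, n_hist_bins = 32) {
  if (length(times_s) == 0L) return(0)
  rp <- presence_ratio(times_s, duration_s, bin_s, mean_fr_ratio)
  ac <- amplitude_cutoff(amplitudes, n_bins = n_hist_bins)
  min(max(rp * (1 - ac), 0), 1)
}

#' Firing-rate metrics
#'
#' Mean firing rate over the recording and the firing-rate range: the
#' difference between the 95th and 5th percentile of per-bin rates with
#' 0.5 s bins (linear-interpolation percentiles).
#'
#' @param times_s Spike times in seconds.
#' @param duration_s Recording length in seconds.
#' @param bin_s Rate-range bin width in seconds.
#' @return Named list `rate` (Hz) and `rate_range` (Hz).
#' @export
firing_rate_metrics <- function(times_s, duration_s, bin_s = 0.5) {
  n_bins <- max(1L, floor(duration_s / bin_s))
  counts <- tabulate(pmin(floor(times_s / bin_s) + 1L, n_bins), nbins = n_bins)
  rates <- counts / bin_s
  q <- stats::quantile(rates, c(0.05, 0.95), names = FALSE, type = 7)
  list(rate = length(times_s) / duration_s, rate_range = q[2] - q[1])
}

#' Firing-rate validity score
#'
#' Product of two logistic terms centred at 200 Hz: one on the mean
#' firing rate, one on the firing-rate range. Rates far above 200 Hz are
#' implausible for motor units and annihilate the score.
#'
#' @param rate Mean firing rate (Hz).
#' @param rate_range 95th minus 5th percentile firing rate (Hz).
#' @return Score in `(0, 1)`.
#' @export
firing_rate_score <- function(rate, rate_range) {
  if (rate < 0 || rate_range < 0) stop("rates must be non-negative")
  (1 / (1 + exp(rate - 200))) * (1 / (1 + exp(rate_range - 200)))
}

#' SNR score
#'
#' `S_SNR = 1 - 1 / (1 + exp(R_SN - 4))`: a sigmoid with midpoint at
#' SNR 4 (value 0.5), heavily penalizing clusters below that level.
#'
#' @param snr Cluster signal-to-noise ratio (>= 0).
#' @return Score in `(0, 1)`.
#' @export
snr_score <- function(snr) {
  if (snr < 0) stop("snr must be non-negative")
  1 - 1 / (1 + exp(snr - 4))
}

#' Cluster SNR from its mean waveform
#'
#' Maximum over channels of the mean-waveform peak magnitude divided by
#' that channel's robust noise SD (MAD-based, using the same 0.6745
#' scaling convention as [estimate_channel_mads()]).
#'
#' @param mean_waveform Matrix `nt x channels`.
#' @param noise_sd Per-channel robust noise SD (> 0).
#' @return SNR value (0 for a zero waveform).
#' @export
compute_snr <- function(mean_waveform, noise_sd) {
  if (any(noise_sd <= 0)) stop("noise SD must be positive")
  peaks <- apply(abs(mean_waveform), 2L, max)
  max(peaks / noise_sd)
}

#' Composite quality report
#'
#' Computes, per cluster, the four component scores (type-I, type-II,
#' firing-rate validity, SNR), their product (the composite score), and
#' the overall sort score: the arithmetic mean of the composites across
#' clusters. All scores live in `[0, 1]`; a single bad component
#' annihilates a cluster's composite.
#'
#' @param sorted A [spike_trains()] tibble of sorter output.
#' @param amplitudes Named list (by cluster) of per-spike amplitudes;
#'   `NULL` falls back to unit amplitudes (amplitude cutoff then reports
#'   0.5 via the edge rule only if degenerate).
#' @param snr Named list or vector (by cluster) of SNR values; `NULL`
#'   uses `Inf` (no SNR penalty), e.g. when waveforms are unavailable.
#' @param refractory_ms,censored_ms Contamination parameters.
#' @return A `quality_report` tibble, one row per cluster, with attribute
#'   `overall`.
#' @export
quality_report <- function(sorted, amplitudes = NULL, snr = NULL,
                           refractory_ms = 1, censored_ms = 0) {
  duration_s <- train_duration(sorted) / train_rate(sorted)
  clusters <- sort(unique(sorted$unit_id))
  if (length(clusters) == 0L) {
    warning("no clusters to score; overall score 0")
    out <- tibble::tibble(cluster = integer(0))
    return(structure(out, overall = 0,
                     class = c("quality_report", class(out))))
  }
  by_cl <- split(sorted$sample_index / train_rate(sorted), sorted$unit_id)
  rows <- lapply(clusters, function(cl) {
    ts <- by_cl[[as.character(cl)]]
    amp <- if (!is.null(amplitudes)) amplitudes[[as.character(cl)]] else
      rep(1, length(ts))
    rc <- llobet_contamination(ts, duration_s, refractory_ms, censored_ms)
    rp <- presence_ratio(ts, duration_s)
    ac <- if (length(unique(amp)) > 1L) amplitude_cutoff(amp) else 0
    fr <- firing_rate_metrics(ts, duration_s)
    sn <- if (!is.null(snr)) snr[[as.character(cl)]] else Inf
    s1 <- 1 - rc
    s2 <- min(max(rp * (1 - ac), 0), 1)
    s3 <- firing_rate_score(fr$rate, fr$rate_range)
    s4 <- if (is.infinite(sn)) 1 else snr_score(sn)
    tibble::tibble(
      cluster = cl, n_spikes = length(ts),
      contamination = rc, presence_ratio = rp, amplitude_cutoff = ac,
      firing_rate = fr$rate, firing_rate_range = fr$rate_range, snr = sn,
      S_T1 = s1, S_T2 = s2, S_FR = s3, S_SNR = s4,
      composite = s1 * s2 * s3 * s4
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, overall = mean(out$composite),
            class = c("quality_report", class(out)))
}

#' Overall score of a quality report
#'
#' @param report A `quality_report`.
#' @return Mean composite score across clusters (0 for no clusters).
#' @export
overall_score <- function(report) {
  attr(report, "overall", exact = TRUE) %||% 0
}

#' Quality-report serialization
#'
#' JSON plus a per-cluster CSV; the overall score is formatted to 4
#' decimals for embedding in output folder names (`.score_<value>`).
#'
#' @param report A `quality_report`.
#' @param prefix Output path prefix.
#' @export
write_quality_report <- function(report, prefix) {
  jsonlite::write_json(
    list(overall = overall_score(report), clusters = as.data.frame(report)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(as.data.frame(report), paste0(prefix, ".csv"),
                   row.names = FALSE)
  invisible(prefix)
}
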