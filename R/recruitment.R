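#' Spike trains as a tidy table
#'
#' Ground-truth (or sorted) spike trains are stored as a tibble with one
#' row per spike: `unit_id` (integer) and `sample_index` (0-based integer
#' sample). The recording length in samples and the sampling rate ride
#' along as attributes.
#'
#' @param unit_id Integer unit labels, one per spike.
#' @param sample_index 0-based spike sample indices.
#' @param duration Recording length in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `spike_trains` tibble sorted by unit then time.
#' @export
spike_trains <- function(unit_id, sample_index, duration, sampling_rate) {
  stopifnot(length(unit_id) == length(sample_index))
  if (any(sample_index < 0 | sample_index >= duration)) {
    stop("spike sample indices must lie in [0, duration)")
  }
  out <- tibble::tibble(unit_id = as.integer(unit_id),
                        sample_index = as.numeric(sample_index))
  out <- dplyr::arrange(out, .data$unit_id, .data$sample_index)
  if (anyDuplicated(out)) stop("duplicate (unit, sample) spike entries")
  structure(out, duration = as.numeric(duration),
            sampling_rate = as.double(sampling_rate),
            class = c("spike_trains", class(out)))
}

#' @rdname spike_trains
#' @param x A `spike_trains` tibble.
#' @return `split_trains()` returns a named list of sorted 0-based sample
#'   vectors, one element per unit.
#' @export
split_trains <- function(x) {
  split(x$sample_index, x$unit_id)
}

train_duration <- function(x) attr(x, "duration", exact = TRUE)
train_rate <- function(x) attr(x, "sampling_rate", exact = TRUE)

#' Sample motor-unit activation thresholds
#'
#' Thresholds follow a shifted exponential law: `theta1 * Exp(lambda = 1)
#' + theta2`, one independent draw per unit. The exponential rate is fixed
#' at 1; `theta1` scales the spread and `theta2` offsets the floor, in the
#' same units as the drive (force) signal.
#'
#' @param n_units Number of motor units.
#' @param theta1 Non-negative scale of the exponential component.
#' @param theta2 Threshold offset.
#' @param seed Integer seed (deterministic draws).
#' @return Numeric vector of `n_units` thresholds.
#' @examples
#' sample_thresholds(5, theta1 = 2, theta2 = 1, seed = 1)
#' @export
sample_thresholds <- function(n_units, theta1, theta2, seed) {
  n_units <- assert_count(n_units, "n_units")
  theta1 <- assert_scalar(theta1, "theta1", min = 0)
  with_seed(substream_seed(seed, "thresholds"),
            theta1 * stats::rexp(n_units, rate = 1) + theta2)
}

#' Build a spike-history kernel
#'
#' The kernel is added to a unit's threshold trace after each spike: a
#' rectangular plateau of height `amplitude` over the absolute refractory
#' span, followed by an exponential decay `amplitude * exp(-t / tau)`
#' (with `t` measured from the refractory end). The kernel is truncated
#' where it falls below 1% of `amplitude`. A plateau exceeding
#' `max(force) - min(thresholds)` makes the refractory period absolute.
#'
#' @param abs_refractory_ms Absolute refractory span in ms (> 0).
#' @param decay_tau_ms Exponential decay time constant in ms.
#' @param amplitude Plateau height, in drive units.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric kernel, `kernel[1] == amplitude`, non-increasing.
#' @export
make_history_kernel <- function(abs_refractory_ms = 1, decay_tau_ms = 20,
                                amplitude = 1, sampling_rate = 30000) {
  if (abs_refractory_ms <= 0) stop("abs_refractory_ms must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  ref_n <- max(1L, round(abs_refractory_ms / 1000 * sampling_rate))
  tau_n <- decay_tau_ms / 1000 * sampling_rate
  decay_n <- ceiling(tau_n * log(100))        # down to 1% of amplitude
  tail <- amplitude * exp(-(seq_len(decay_n)) / tau_n)
  kernel <- c(rep(amplitude, ref_n), tail[tail > 0.01 * amplitude])
  structure(kernel, refractory_samples = ref_n)
}

#' Motor pool configuration
#'
#' Bundles everything the recruitment simulator needs: per-unit activation
#' thresholds (drawn by [sample_thresholds()]), the spike-history kernel
#' parameters, and the seed driving the per-sample binomial draws. When
#' `kernel_amplitude` is `NULL` it is resolved at generation time as
#' `10 * (max(force) - min(thresholds))`, which makes the refractory
#' plateau absolute for any drive the pool will see.
#'
#' @inheritParams sample_thresholds
#' @inheritParams make_history_kernel
#' @param kernel_amplitude Plateau height or `NULL` for the automatic rule.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `motor_pool` object.
#' @export
motor_pool <- function(n_units = 10, theta1 = 2, theta2 = 1,
                       abs_refractory_ms = 1, decay_tau_ms = 20,
                       kernel_amplitude = NULL, sampling_rate = 30000,
                       seed = 1) {
  thresholds <- sample_thresholds(n_units, theta1, theta2, seed)
  structure(
    list(n_units = as.integer(n_units), theta1 = theta1, theta2 = theta2,
         thresholds = thresholds, abs_refractory_ms = abs_refractory_ms,
         decay_tau_ms = decay_tau_ms, kernel_amplitude = kernel_amplitude,
         sampling_rate = as.double(sampling_rate), seed = as.integer(seed)),
    class = "motor_pool"
  )
}

#' Synthetic drive (force) signal
#'
#' Emulates the envelope of locomotor drive: rectified low-pass-filtered
#' noise superposed on periodic raised-cosine bursts (step cycles). Any
#' user-supplied non-negative array can be used instead.
#'
#' @param duration_s Length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param step_hz Burst (step-cycle) frequency in Hz.
#' @param amplitude Peak drive level.
#' @param noise_sd Standard deviation of the slow noise component.
#' @param seed Integer seed.
#' @return A `force_signal`: list with `samples` and `sampling_rate`.
#' @export
make_force_signal <- function(duration_s = 10, sampling_rate = 30000,
                              step_hz = 2, amplitude = 6, noise_sd = 0.15,
                              seed = 1) {
  n <- round(duration_s * sampling_rate)
  t <- seq_len(n) / sampling_rate
  bursts <- amplitude * (0.5 - 0.5 * cos(2 * pi * step_hz * t))^2
  slow <- with_seed(substream_seed(seed, "force"), {
    x <- stats::rnorm(n)
    bf <- signal::butter(2, min(0.5, 5 / (sampling_rate / 2)), type = "low")
    as.numeric(signal::filtfilt(bf, x))
  })
  slow <- slow / max(stats::sd(slow), .Machine$double.eps) * noise_sd * amplitude
  force_signal(pmax(bursts + slow, 0), sampling_rate)
}

#' @rdname make_force_signal
#' @param samples Numeric drive values (finite, length >= 1).
#' @export
force_signal <- function(samples, sampling_rate) {
  if (length(samples) < 1L || !all(is.finite(samples))) {
    stop("force signal must be non-empty and finite")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.double(sampling_rate)),
            class = "force_signal")
}

#' Generate ground-truth spike trains from a drive signal
#'
#' Implements the recruitment algorithm: at each time step a unit is
#' eligible only while the drive exceeds its (time-varying) threshold
#' trace; an eligible unit fires with probability
#' `sigmoid(force - threshold)`; after a spike the history kernel is added
#' to that unit's threshold trace over the following `length(kernel)`
#' samples, enforcing the refractory period and capping the attainable
#' rate. Units evolve in parallel; time advances strictly sequentially.
#'
#' @param pool A [motor_pool()].
#' @param force A [force_signal()] with the same sampling rate.
#' @param keep_response_curves If `TRUE`, attach the per-unit response
#'   curves (`force - threshold trace`) as an attribute (diagnostic; costs
#'   `duration x n_units` doubles).
#' @return A [spike_trains()] tibble with attributes `duration` and
#'   `sampling_rate`.
#' @export
generate_spike_trains <- function(pool, force, keep_response_curves = FALSE) {
  if (!inherits(pool, "motor_pool")) stop("`pool` must be a motor_pool")
  if (!inherits(force, "force_signal")) stop("`force` must be a force_signal")
  if (pool$sampling_rate != force$sampling_rate) {
    stop("pool and force sampling rates differ")
  }
  f <- force$samples
  n_t <- length(f)
  if (n_t == 0L) stop("empty force signal")
  u <- pool$n_units
  th0 <- pool$thresholds

  amp <- pool$kernel_amplitude %||% (10 * max(max(f) - min(th0), 1))
  kernel <- make_history_kernel(pool$abs_refractory_ms, pool$decay_tau_ms,
                                amplitude = amp,
                                sampling_rate = pool$sampling_rate)
  klen <- length(kernel)

  # additive threshold increments scheduled by past spikes
  bump <- matrix(0, nrow = u, ncol = n_t + klen)
  spikes_u <- vector("list", u)
  counts <- integer(u)
  for (i in seq_len(u)) spikes_u[[i]] <- numeric(512)
  resp <- if (keep_response_curves) matrix(NA_real_, n_t, u) else NULL

  with_seed(substream_seed(pool$seed, "binomial"), {
    for (t in seq_len(n_t)) {
      th_t <- th0 + bump[, t]
      d <- f[t] - th_t
      if (keep_response_curves) resp[t, ] <- d
      eligible <- which(d > 0)
      if (length(eligible)) {
        p <- sigmoid(d[eligible])
        fired <- eligible[stats::runif(length(eligible)) < p]
        for (i in fired) {
          counts[i] <- counts[i] + 1L
          if (counts[i] > length(spikes_u[[i]])) {
            spikes_u[[i]] <- c(spikes_u[[i]], numeric(length(spikes_u[[i]])))
          }
          spikes_u[[i]][counts[i]] <- t - 1L   # 0-based
          idx <- t:min(t + klen - 1L, n_t + klen)
          bump[i, idx] <- bump[i, idx] + kernel[seq_along(idx)]
        }
      }
    }
  })

  unit_id <- rep(seq_len(u), counts)
  samp <- unlist(lapply(seq_len(u), function(i) spikes_u[[i]][seq_len(counts[i])]),
                 use.names = FALSE)
  out <- spike_trains(unit_id, samp, duration = n_t,
                      sampling_rate = pool$sampling_rate)
  if (keep_response_curves) attr(out, "response_curves") <- resp
  out
}

#' Ground-truth CSV round trip
#'
#' Ground truth is written as CSV with header `unit_id,sample_index`
#' (0-based sample indices).
#'
#' @param x A `spike_trains` tibble.
#' @param path File path.
#' @export
write_ground_truth <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("unit_id", "sample_index")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @param duration,sampling_rate Recording length (samples) and rate (Hz);
#'   `duration = NULL` infers `max(sample_index) + 1`.
#' @export
read_ground_truth <- function(path, duration = NULL, sampling_rate = 30000) {
  df <- utils::read.csv(path)
  if (!all(c("unit_id", "sample_index") %in% names(df))) {
    stop("ground-truth CSV must have columns unit_id,sample_index")
  }
  spike_trains(df$unit_id, df$sample_index,
               duration = duration %||% (max(df$sample_index) + 1),
               sampling_rate = sampling_rate)
}
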