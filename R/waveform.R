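#' Morphing configuration
#'
#' Per-spike waveform variability is modelled by elementwise Gaussian
#' gains on the channel weights: each spike draws `G ~ N(gain_mean,
#' gain_sd)` of the same shape as the unit's weight matrix. Windowing uses
#' a zero-padded Tukey window: `pad_fraction` of the window is exactly
#' zero on each side and the central `flat_fraction` carries the Tukey
#' taper, so `2 * pad_fraction + flat_fraction == 1`.
#'
#' @param gain_mean,gain_sd Gaussian gain parameters (defaults 1 and 0.2).
#' @param tukey_alpha Tukey taper parameter.
#' @param flat_fraction,pad_fraction Window layout fractions.
#' @return A `morph_config` list.
#' @export
morph_config <- function(gain_mean = 1, gain_sd = 0.2, tukey_alpha = 0.25,
                         flat_fraction = 0.9, pad_fraction = 0.05) {
  if (gain_sd < 0) stop("gain_sd must be >= 0")
  if (abs(2 * pad_fraction + flat_fraction - 1) > 1e-9) {
    stop("2 * pad_fraction + flat_fraction must equal 1")
  }
  structure(list(gain_mean = gain_mean, gain_sd = gain_sd,
                 tukey_alpha = tukey_alpha, flat_fraction = flat_fraction,
                 pad_fraction = pad_fraction),
            class = "morph_config")
}

#' Morph one spike instance of a unit's template
#'
#' `M = b * t(w_inv %*% ((U0_i (*) G) %*% W))`: the unit's channel weights
#' are perturbed elementwise by the gain draw `G`, projected through the
#' temporal components, un-whitened across channels and scaled to voltage
#' units. With `G == 1`, `b == 1` and identity `w_inv` this is exactly the
#' unit's template.
#'
#' @param basis A [muap_basis()].
#' @param unit Unit index.
#' @param G Gain matrix `n_channels x n_pcs`.
#' @return Waveform matrix `nt x n_channels`.
#' @export
morph_waveform <- function(basis, unit, G) {
  U <- basis$U0[unit, , , drop = TRUE]
  dim(U) <- c(basis$n_channels, basis$n_pcs)
  if (!identical(dim(G), dim(U))) {
    stop("G must be ", basis$n_channels, " x ", basis$n_pcs)
  }
  basis$b * t(basis$w_inv %*% ((U * G) %*% basis$W))
}

#' Zero-padded Tukey window
#'
#' Zeros over the first and last `round(pad_fraction * nt)` samples, a
#' Tukey(`alpha`) taper over the centre, peak value 1. The taper is
#' sampled so that its own endpoints are nonzero; the only exact zeros are
#' the pads, and every placed spike therefore contributes exactly 0 at its
#' window edges.
#'
#' @param nt Window length in samples (>= 5).
#' @param alpha Tukey taper parameter.
#' @param pad_fraction Zero-pad fraction per side.
#' @return Numeric window of length `nt`.
#' @export
tukey_window <- function(nt, alpha = 0.25, pad_fraction = 0.05) {
  nt <- assert_count(nt, "nt", min = 5L)
  pad <- round(pad_fraction * nt)
  m <- nt - 2L * pad
  if (m < 3L) stop("nt too small for the requested padding")
  # sample a length-(m+2) Tukey window and drop its zero endpoints
  L <- m + 2L
  x <- (seq_len(L) - 1) / (L - 1)
  w <- rep(1, L)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  c(rep(0, pad), w[2:(L - 1L)], rep(0, pad))
}

# 0-based window sample at which the spike time sits (one third in).
spike_center_offset <- function(nt) floor(nt / 3)

#' Superpose morphed spikes into a noiseless data matrix
#'
#' Each ground-truth spike draws its own gain matrix, is morphed through
#' the basis, windowed, and added at its spike time (window sample
#' `floor(nt/3)` aligned to the spike sample). Overlapping spikes sum;
#' spikes whose window exceeds the recording edge are truncated, not
#' dropped.
#'
#' @param duration Recording length in samples.
#' @param trains A [spike_trains()] tibble.
#' @param basis A [muap_basis()].
#' @param config A [morph_config()].
#' @param seed Integer seed for the gain draws.
#' @return Numeric matrix `duration x n_channels`.
#' @export
superpose_spikes <- function(duration, trains, basis, config = morph_config(),
                             seed = 1) {
  D <- matrix(0, nrow = duration, ncol = basis$n_channels)
  if (nrow(trains) == 0L) return(D)
  win <- tukey_window(basis$nt, config$tukey_alpha, config$pad_fraction)
  off <- spike_center_offset(basis$nt)
  cp <- basis$n_channels * basis$n_pcs
  root <- substream_seed(seed, "morph")
  for (r in seq_len(nrow(trains))) {
    u <- trains$unit_id[r]
    s <- trains$sample_index[r]                # 0-based
    # gains keyed by spike identity: superposition is additive across
    # disjoint trains and independent of spike order
    G <- with_seed(substream_seed(root, sprintf("gain-%d-%.0f", u, s)),
                   matrix(stats::rnorm(cp, config$gain_mean, config$gain_sd),
                          basis$n_channels, basis$n_pcs))
    M <- morph_waveform(basis, u, G) * win
    t0 <- s - off + 1                          # 1-based start row
    rows <- t0:(t0 + basis$nt - 1L)
    ok <- rows >= 1L & rows <= duration
    D[rows[ok], ] <- D[rows[ok], ] + M[ok, , drop = FALSE]
  }
  D
}

# Row indices of the chunked subset used for MAD estimation: `n_chunks`
# evenly spaced chunks of `chunk_s` seconds (whole recording if shorter).
chunk_indices <- function(n, sampling_rate, n_chunks = 20, chunk_s = 1) {
  chunk_len <- round(chunk_s * sampling_rate)
  if (n <= n_chunks * chunk_len) return(seq_len(n))
  starts <- floor(seq(0, n - chunk_len, length.out = n_chunks))
  unique(as.vector(outer(seq_len(chunk_len), starts, `+`)))
}

#' Standardized per-channel MAD noise estimate
#'
#' `median(|x - median(x)|) / 0.6745` per channel, evaluated on a chunked
#' subset of the recording (by default 20 evenly spaced 1-s chunks); the
#' 0.6745 factor makes the MAD estimate the standard deviation for
#' Gaussian data.
#'
#' @param D Data matrix `time x channels`.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_chunks,chunk_s Chunk geometry for the subset.
#' @return Numeric vector of per-channel noise estimates.
#' @export
estimate_channel_mads <- function(D, sampling_rate = 30000, n_chunks = 20,
                                  chunk_s = 1) {
  idx <- chunk_indices(nrow(D), sampling_rate, n_chunks, chunk_s)
  C <- D[idx, , drop = FALSE]
  vapply(seq_len(ncol(C)), function(ch) {
    x <- C[, ch]
    stats::median(abs(x - stats::median(x))) / MAD_SCALE
  }, numeric(1))
}

#' Fit per-channel additive noise to target MAD levels
#'
#' Learns one Gaussian noise standard deviation per channel so that the
#' augmented recording `D + G * sigma_L` reproduces target standardized
#' MAD values. The per-channel sigmas are the only learnable parameters,
#' updated by an Adam optimizer (learning rate 1) on the mean squared
#' error between current and target MADs; fresh Gaussian noise is redrawn
#' at every iteration, and learning stops when every channel's MAD is
#' within `tol` (1%) relative of its target, or after `max_iter` (3000)
#' iterations, in which case the fit is flagged unconverged with a
#' warning.
#'
#' @param D Noiseless data matrix `time x channels`.
#' @param targets Positive per-channel target MAD levels.
#' @param seed Integer seed (per-iteration noise substreams).
#' @param sampling_rate Sampling rate in Hz.
#' @param lr Adam learning rate.
#' @param max_iter Iteration cap.
#' @param tol Relative convergence tolerance.
#' @param n_chunks,chunk_s Chunk geometry for the MAD estimates.
#' @return List with `data` (the augmented matrix) and `fit` (a
#'   `noise_fit`: targets, learned sigmas, loss trace, iterations,
#'   `converged` flag).
#' @export
fit_noise_levels <- function(D, targets, seed = 1, sampling_rate = 30000,
                             lr = 1, max_iter = 3000, tol = 0.01,
                             n_chunks = 20, chunk_s = 1) {
  n_ch <- ncol(D)
  if (length(targets) != n_ch) stop("one MAD target per channel required")
  if (any(targets <= 0)) stop("MAD targets must be positive")
  idx <- chunk_indices(nrow(D), sampling_rate, n_chunks, chunk_s)

  # initialize at the targets: on sparse spike data the MAD subgradient
  # vanishes at sigma = 0, and the targets are the natural first guess
  sigmaL <- as.numeric(targets)
  m <- numeric(n_ch); v <- numeric(n_ch)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  D_aug <- NULL

  root <- substream_seed(seed, "noise-fit")
  for (it in seq_len(max_iter)) {
    iterations <- it
    # fresh full-length noise every iteration; the chunked subset of the
    # same realization drives the MAD estimates, so the returned D_aug is
    # exactly the realization that satisfied the stop rule
    G <- with_seed(substream_seed(root, paste0("iter", it)),
                   matrix(stats::rnorm(length(D)), nrow(D), n_ch))
    D_aug <- D + sweep(G, 2L, sigmaL, `*`)
    sS <- numeric(n_ch); grad_s <- numeric(n_ch)
    for (ch in seq_len(n_ch)) {
      x <- D_aug[idx, ch]
      med <- stats::median(x)
      dev <- abs(x - med)
      sS[ch] <- stats::median(dev) / MAD_SCALE
      # subgradient of the MAD through its attaining order statistics
      k <- which.min(abs(dev - stats::median(dev)))
      q <- which.min(dev)
      grad_s[ch] <- sign(x[k] - med) * (G[idx[k], ch] - G[idx[q], ch]) / MAD_SCALE
    }
    loss <- mean((sS - targets)^2)
    loss_trace[it] <- loss
    if (all(abs(sS - targets) / targets <= tol)) {
      converged <- TRUE
      break
    }
    g <- 2 * (sS - targets) / n_ch * grad_s
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    sigmaL <- abs(sigmaL - lr * mhat / (sqrt(vhat) + eps))
  }
  if (!converged) {
    warning("noise fit did not converge within ", max_iter, " iterations")
  }
  fit <- structure(
    list(targets = targets, learned = sigmaL, loss = loss_trace,
         iterations = iterations, converged = converged,
         lr = lr, max_iter = max_iter, tol = tol),
    class = "noise_fit"
  )
  list(data = D_aug, fit = fit)
}

#' Simulate a full multichannel MUAP recording with ground truth
#'
#' Runs recruitment, waveform superposition, and (optionally) the noise
#' fit end to end, returning the data matrix together with the
#' ground-truth spike trains and the noise-fit record. Fully reproducible
#' under `seed`.
#'
#' @param basis A [muap_basis()].
#' @param pool A [motor_pool()].
#' @param force A [force_signal()].
#' @param config A [morph_config()].
#' @param noise_targets Per-channel target MAD levels, or `NULL` for a
#'   noiseless recording.
#' @param seed Integer root seed.
#' @param ... Passed on to [fit_noise_levels()].
#' @return A `muap_recording`: list with `data`, `sampling_rate`,
#'   `ground_truth`, `noise_fit`, `basis`, `seed`.
#' @export
simulate_recording <- function(basis, pool, force, config = morph_config(),
                               noise_targets = NULL, seed = 1, ...) {
  if (basis$sampling_rate != pool$sampling_rate) {
    stop("basis and pool sampling rates differ")
  }
  trains <- generate_spike_trains(pool, force)
  duration <- train_duration(trains)
  D <- superpose_spikes(duration, trains, basis, config,
                        seed = substream_seed(seed, "superpose"))
  fit <- NULL
  if (!is.null(noise_targets)) {
    res <- fit_noise_levels(D, noise_targets,
                            seed = substream_seed(seed, "noise"),
                            sampling_rate = basis$sampling_rate, ...)
    D <- res$data
    fit <- res$fit
  }
  structure(
    list(data = D, sampling_rate = basis$sampling_rate,
         ground_truth = trains, noise_fit = fit, basis = basis,
         seed = as.integer(seed)),
    class = "muap_recording"
  )
}

#' Rat-like and monkey-like simulation presets
#'
#' Convenience constructors matching the two reference dataset geometries:
#' `"rat"` simulates 10 motor units over 8 channels with a 61-sample
#' (2 ms at 30 kHz) spike window; `"monkey"` 5 units over 16 channels
#' with a 121-sample (4 ms) window.
#'
#' @param preset `"rat"` or `"monkey"`.
#' @param duration_s Recording length in seconds.
#' @param noise_targets Per-channel MAD targets (`NULL` = noiseless).
#' @param seed Integer seed.
#' @return A `muap_recording`.
#' @export
simulate_preset <- function(preset = c("rat", "monkey"), duration_s = 10,
                            noise_targets = NULL, seed = 1) {
  preset <- match.arg(preset)
  p <- switch(preset,
    rat = list(n_units = 10L, n_channels = 8L, nt = 61L),
    monkey = list(n_units = 5L, n_channels = 16L, nt = 121L)
  )
  basis <- make_synthetic_basis(n_units = p$n_units, n_channels = p$n_channels,
                                nt = p$nt, n_pcs = 9, max_delay = p$nt %/% 5,
                                seed = substream_seed(seed, "basis"))
  pool <- motor_pool(n_units = p$n_units, seed = substream_seed(seed, "pool"))
  force <- make_force_signal(duration_s = duration_s,
                             seed = substream_seed(seed, "force"))
  simulate_recording(basis, pool, force, noise_targets = noise_targets,
                     seed = substream_seed(seed, "recording"))
}

#' Flat-binary recording round trip
#'
#' Writes the data matrix as flat little-endian int16 (time-major,
#' channel-interleaved) with a JSON sidecar `{sampling_rate, n_channels,
#' dtype, scale_to_uV}`, and the ground truth (if present) as CSV.
#'
#' @param rec A `muap_recording` (or bare matrix plus `sampling_rate`).
#' @param prefix Output path prefix; writes `<prefix>.bin`,
#'   `<prefix>.json` and (for recordings with truth) `<prefix>_truth.csv`.
#' @export
write_recording <- function(rec, prefix) {
  D <- if (inherits(rec, "muap_recording")) rec$data else rec
  rate <- if (inherits(rec, "muap_recording")) rec$sampling_rate else
    attr(rec, "sampling_rate")
  scale <- max(abs(D), .Machine$double.eps) / 32000
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.integer(round(t(D) / scale)), con, size = 2L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(sampling_rate = rate, n_channels = ncol(D), dtype = "int16",
         scale_to_uV = scale),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  if (inherits(rec, "muap_recording")) {
    write_ground_truth(rec$ground_truth, paste0(prefix, "_truth.csv"))
  }
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sz <- file.info(paste0(prefix, ".bin"))$size
  con <- file(paste0(prefix, ".bin"), "rb")
  raw_vals <- readBin(con, "integer", n = sz / 2, size = 2L, endian = "little")
  close(con)
  D <- t(matrix(raw_vals * meta$scale_to_uV, nrow = as.integer(meta$n_channels)))
  attr(D, "sampling_rate") <- as.numeric(meta$sampling_rate)
  D
}

#' @export
print.muap_recording <- function(x, ...) {
  cat(sprintf(
    "<muap_recording> %.1f s x %d channels at %g Hz; %d ground-truth spikes from %d units%s\n",
    nrow(x$data) / x$sampling_rate, ncol(x$data), x$sampling_rate,
    nrow(x$ground_truth), length(unique(x$ground_truth$unit_id)),
    if (is.null(x$noise_fit)) " (noiseless)" else
      sprintf("; noise fit %s in %d iterations",
              if (x$noise_fit$converged) "converged" else "NOT converged",
              x$noise_fit$iterations)
  ))
  invisible(x)
}
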