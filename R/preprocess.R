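#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase)
#' to every channel; DC is rejected. The default passband of 250-5000 Hz
#' targets intramuscular EMG.
#'
#' @param D Data matrix `time x channels` (a vector is treated as one
#'   channel).
#' @param low,high Band edges in Hz; `0 < low < high < sampling_rate / 2`.
#' @param sampling_rate Sampling rate in Hz.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(D, low = 250, high = 5000, sampling_rate = 30000) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("invalid band: need 0 < low < high < Nyquist")
  }
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  apply_filter(D, bf)
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (Q = 30) applied forward-backward, rejecting
#' mains interference; defaults to 60 Hz and is configurable to 50 Hz.
#'
#' @inheritParams bandpass_filter
#' @param freq Notch frequency in Hz (< Nyquist).
#' @param Q Quality factor of the notch.
#' @export
notch_filter <- function(D, freq = 60, sampling_rate = 30000, Q = 30) {
  nyq <- sampling_rate / 2
  if (!(freq > 0 && freq < nyq)) stop("invalid notch frequency")
  w0 <- 2 * pi * freq / sampling_rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_filter(D, list(b = b, a = a))
}

apply_filter <- function(D, flt) {
  vec <- is.null(dim(D))
  if (vec) D <- matrix(D, ncol = 1L)
  out <- apply(D, 2L, function(x) {
    as.numeric(signal::filtfilt(flt$b, flt$a, x))
  })
  if (vec) as.numeric(out) else out
}

#' Detect bad channels by robust deviation
#'
#' A channel is rejected when its deviation statistic (robust MAD-based
#' SD for `mad` methods, plain standard deviation for `std` methods)
#' exceeds `k` times the cross-channel median of that statistic. The
#' method string encodes the statistic and threshold, e.g. the default
#' `"mad5"` (MAD statistic, threshold 5); bare `"mad"`/`"std"` use
#' threshold 5.
#'
#' @param D Data matrix `time x channels` (>= 2 channels).
#' @param method Method string: `'mad'`, `'std'`, `'mad#'` or `'std#'`.
#' @return Logical keep mask, one entry per channel.
#' @export
detect_bad_channels <- function(D, method = "mad5") {
  if (ncol(D) < 2L) stop("need at least 2 channels")
  m <- regmatches(method, regexec("^(mad|std)([0-9.]*)$", method))[[1]]
  if (length(m) == 0L) stop("unknown bad-channel method: ", method)
  k <- if (nzchar(m[3])) as.numeric(m[3]) else 5
  stat <- if (m[2] == "mad") {
    apply(D, 2L, function(x) stats::median(abs(x - stats::median(x))) / MAD_SCALE)
  } else {
    apply(D, 2L, stats::sd)
  }
  stat <= k * stats::median(stat)
}

#' Whiten channels
#'
#' Symmetric (ZCA) whitening so the output channel covariance is
#' approximately the identity. With `whitening_range` smaller than the
#' channel count, each channel's whitening row is estimated from its
#' nearest channels only (local whitening on the linear map). The inverse
#' matrix is returned for simulation round trips.
#'
#' @param D Data matrix `time x channels`.
#' @param whitening_range Number of nearby channels used to estimate each
#'   whitening row.
#' @return List with `data` (whitened matrix), `W` (whitening matrix) and
#'   `W_inv`.
#' @export
whiten <- function(D, whitening_range = 32) {
  n_ch <- ncol(D)
  if (nrow(D) < 2L * n_ch) stop("not enough samples to estimate covariance")
  Dc <- sweep(D, 2L, colMeans(D))
  CC <- crossprod(Dc) / (nrow(D) - 1)
  eps <- 1e-6 * mean(diag(CC))
  zca <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values)) {
      warning("rank-deficient channel covariance; regularizing")
    }
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 0) + eps),
                       length(e$values)) %*% t(e$vectors)
  }
  if (whitening_range >= n_ch) {
    W <- zca(CC)
  } else {
    W <- matrix(0, n_ch, n_ch)
    half <- whitening_range %/% 2
    for (i in seq_len(n_ch)) {
      lo <- max(1L, min(i - half, n_ch - whitening_range + 1L))
      nb <- lo:min(lo + whitening_range - 1L, n_ch)
      Wsub <- zca(CC[nb, nb, drop = FALSE])
      W[i, nb] <- Wsub[match(i, nb), ]
    }
  }
  list(data = Dc %*% t(W), W = W, W_inv = solve(W))
}

#' Estimate cross-channel conduction delays
#'
#' Builds the 3-D matrix of Pearson correlations between every channel
#' pair at every integer lag in `[-max_lag, +max_lag]` samples (the
#' default of 2 ms corresponds to +/-60 samples at 30 kHz). The best
#' shift for each pair is the lag maximizing the correlation (ties broken
#' toward the smaller `|lag|`, then toward the negative lag); the
#' reference channel is the row whose best correlations sum highest (ties
#' toward the lowest index), and the returned shifts are that row's best
#' lags.
#'
#' @param D Data matrix `time x channels` (>= 2 channels).
#' @param max_lag_ms Maximum lag magnitude in ms.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `delay_plan`: `reference`, per-channel `shifts` (reference
#'   shift 0), `correlation_matrix` (`channels x channels x lags`),
#'   `best_shift_matrix`, `max_lag`, `sampling_rate`.
#' @export
estimate_channel_delays <- function(D, max_lag_ms = 2, sampling_rate = 30000) {
  n_ch <- ncol(D)
  if (n_ch < 2L) stop("need at least 2 channels")
  L <- round(max_lag_ms / 1000 * sampling_rate)
  if (nrow(D) <= 2L * L) stop("recording shorter than twice the maximum lag")
  lags <- -L:L
  corr <- array(0, dim = c(n_ch, n_ch, length(lags)),
                dimnames = list(NULL, NULL, lags))
  for (i in seq_len(n_ch)) {
    for (j in seq_len(n_ch)) {
      corr[i, j, ] <- lagged_correlations(D[, i], D[, j], lags)
    }
  }
  best <- matrix(0L, n_ch, n_ch)
  bestval <- matrix(0, n_ch, n_ch)
  # tie-break preference: smaller |lag| first, then negative before positive
  pref <- order(abs(lags), lags)
  for (i in seq_len(n_ch)) {
    for (j in seq_len(n_ch)) {
      v <- corr[i, j, pref]
      k <- pref[which.max(v)]
      best[i, j] <- lags[k]
      bestval[i, j] <- corr[i, j, k]
    }
  }
  ref <- which.max(rowSums(bestval))           # first index wins ties
  structure(
    list(reference = as.integer(ref), shifts = best[ref, ],
         correlation_matrix = corr, best_shift_matrix = best,
         max_lag = L, sampling_rate = sampling_rate),
    class = "delay_plan"
  )
}

# Pearson correlation of x[t] with y[t + lag] over the overlapping span;
# zero-variance overlap yields 0.
lagged_correlations <- function(x, y, lags) {
  n <- length(x)
  vapply(lags, function(l) {
    if (l >= 0) {
      xi <- x[seq_len(n - l)]; yi <- y[seq_len(n - l) + l]
    } else {
      xi <- x[seq_len(n + l) - l]; yi <- y[seq_len(n + l)]
    }
    sx <- stats::sd(xi); sy <- stats::sd(yi)
    if (sx == 0 || sy == 0) 0 else stats::cor(xi, yi)
  }, numeric(1))
}

#' Apply a delay plan
#'
#' Each channel is rolled by its shift (`out[t] = in[t + shift]`); vacated
#' edge samples are set to 0.
#'
#' @param D Data matrix `time x channels`.
#' @param plan A `delay_plan` (or bare integer shift vector).
#' @return Aligned matrix of the same shape.
#' @export
apply_channel_delays <- function(D, plan) {
  shifts <- if (inherits(plan, "delay_plan")) plan$shifts else as.integer(plan)
  if (length(shifts) != ncol(D)) stop("plan channel count does not match data")
  n <- nrow(D)
  if (any(abs(shifts) >= n)) stop("shift exceeds data length")
  out <- matrix(0, n, ncol(D))
  for (ch in seq_len(ncol(D))) {
    s <- shifts[ch]
    if (s >= 0) {
      out[seq_len(n - s), ch] <- D[seq_len(n - s) + s, ch]
    } else {
      out[seq_len(n + s) - s, ch] <- D[seq_len(n + s), ch]
    }
  }
  out
}

#' Dense linear channel map
#'
#' Minimal-size 1-D map with 2 micrometre spacing: positions 0, 2, 4, ...
#'
#' @param n_channels Number of channels (>= 1).
#' @param spacing_um Spacing in micrometres.
#' @return Tibble with `channel` and `position_um`.
#' @export
make_channel_map <- function(n_channels, spacing_um = 2) {
  n_channels <- assert_count(n_channels, "n_channels")
  tibble::tibble(channel = seq_len(n_channels),
                 position_um = (seq_len(n_channels) - 1) * spacing_um)
}

#' Delay-plan JSON round trip
#'
#' @param plan A `delay_plan`.
#' @param path File path.
#' @export
write_delay_plan <- function(plan, path) {
  jsonlite::write_json(
    list(reference_channel = plan$reference, shifts = plan$shifts,
         max_lag = plan$max_lag, sampling_rate = plan$sampling_rate),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_delay_plan
#' @export
read_delay_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(reference = as.integer(x$reference_channel),
         shifts = as.integer(x$shifts),
         correlation_matrix = NULL, best_shift_matrix = NULL,
         max_lag = as.integer(x$max_lag), sampling_rate = x$sampling_rate),
    class = "delay_plan"
  )
}
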