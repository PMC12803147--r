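# Preprocessing: filters, bad channels, whitening, delays, channel map.

fs <- 30000
sine <- function(f, n = fs) sin(2 * pi * f * seq_len(n) / fs)
mid <- 5000:25000                              # steady-state span

test_that("band-pass filter passes the band and rejects DC and drift", {
  dc <- matrix(2, fs, 2)
  out <- bandpass_filter(dc, sampling_rate = fs)
  expect_lt(max(abs(out[mid, ])), 1e-6 * 2)   # steady state: DC fully rejected
  g1k <- sd(bandpass_filter(sine(1000), sampling_rate = fs)[mid]) /
    sd(sine(1000)[mid])
  expect_lt(abs(g1k - 1), 0.05)
  att10 <- 20 * log10(sd(bandpass_filter(sine(10), sampling_rate = fs)[mid]) /
                        sd(sine(10)[mid]))
  expect_lt(att10, -20)
  expect_error(bandpass_filter(dc, low = 5000, high = 250), "band")
})

test_that("notch filter rejects mains frequency and spares the passband", {
  att60 <- 20 * log10(sd(notch_filter(sine(60, 2 * fs),
                                      sampling_rate = fs)[mid + fs / 2]) /
                        sd(sine(60, 2 * fs)[mid + fs / 2]))
  expect_lt(att60, -20)
  g1k <- sd(notch_filter(sine(1000), sampling_rate = fs)[mid]) /
    sd(sine(1000)[mid])
  expect_lt(abs(g1k - 1), 0.02)
  # configurable to 50 Hz
  att50 <- 20 * log10(sd(notch_filter(sine(50, 2 * fs), freq = 50,
                                      sampling_rate = fs)[mid + fs / 2]) /
                        sd(sine(50, 2 * fs)[mid + fs / 2]))
  expect_lt(att50, -20)
  expect_error(notch_filter(matrix(0, 100, 1), freq = 2e5), "freq")
})

test_that("bad-channel detection flags high-deviation channels only", {
  base <- withr::with_seed(5, matrix(rnorm(20000 * 6), ncol = 6))
  expect_true(all(detect_bad_channels(base, "mad5")))
  noisy <- base
  noisy[, 4] <- noisy[, 4] * 10
  keep <- detect_bad_channels(noisy, "mad5")
  expect_identical(which(!keep), 4L)
  # oracle: direct MAD ratio
  stats <- apply(noisy, 2, oracle_mad)
  expect_identical(keep, stats <= 5 * median(stats))
  # std variant and threshold parsing
  expect_identical(which(!detect_bad_channels(noisy, "std3")), 4L)
  expect_error(detect_bad_channels(noisy, "median5"), "unknown")
})

test_that("whitening decorrelates channels and returns a true inverse", {
  mix <- matrix(c(2, 1, 0.3, 1, 2, 0.5, 0.3, 0.5, 1.5), 3)
  X <- withr::with_seed(6, matrix(rnorm(1e5 * 3), ncol = 3) %*% mix)
  w <- whiten(X)
  cv <- stats::cov(w$data)
  expect_lt(max(abs(diag(cv) - 1)), 0.02)
  expect_lt(max(abs(cv[upper.tri(cv)])), 0.05)
  expect_lt(max(abs(w$W %*% w$W_inv - diag(3))), 1e-8)
  # near-identity on already-white input
  Xw <- withr::with_seed(7, matrix(rnorm(1e5 * 3), ncol = 3))
  expect_lt(max(abs(whiten(Xw)$W - diag(3))), 0.05)
  # local whitening keeps rows supported on nearby channels
  X8 <- withr::with_seed(8, matrix(rnorm(4e4 * 8), ncol = 8))
  wl <- whiten(X8, whitening_range = 4)
  expect_equal(wl$W[1, 6:8], c(0, 0, 0))
})

test_that("planted integer delays are recovered exactly", {
  withr::with_seed(9, {
    n <- 30000
    base <- as.numeric(stats::filter(rnorm(n + 200), rep(1, 5), sides = 2))
    base[is.na(base)] <- 0
    true_shift <- c(0L, 5L, -12L, 30L)
    D <- vapply(true_shift, function(s) base[seq_len(n) + 100 - s], numeric(n))
  })
  plan <- estimate_channel_delays(D, max_lag_ms = 2, sampling_rate = fs)
  rel <- plan$shifts - plan$shifts[plan$reference]
  expect_identical(as.integer(rel), true_shift - true_shift[plan$reference])
  # alignment closes the loop: per-channel peaks coincide after applying
  Da <- apply_channel_delays(D, plan)
  peaks <- apply(abs(Da[2000:28000, ]), 2, which.max)
  expect_identical(diff(range(peaks)), 0L)
})

test_that("delay estimation agrees with exhaustive search on small instances", {
  # brute force over every (reference, lag) pair, written independently
  brute_plan <- function(D, L) {
    n_ch <- ncol(D); lags <- -L:L
    n <- nrow(D)
    corr_at <- function(i, j, l) {
      if (l >= 0) {
        xi <- D[1:(n - l), i]; yj <- D[(1 + l):n, j]
      } else {
        xi <- D[(1 - l):n, i]; yj <- D[1:(n + l), j]
      }
      if (sd(xi) == 0 || sd(yj) == 0) 0 else cor(xi, yj)
    }
    best <- matrix(0L, n_ch, n_ch); bv <- matrix(-Inf, n_ch, n_ch)
    for (i in 1:n_ch) for (j in 1:n_ch) {
      for (l in lags[order(abs(lags), lags)]) {
        v <- corr_at(i, j, l)
        if (v > bv[i, j]) { bv[i, j] <- v; best[i, j] <- l }
      }
    }
    ref <- which.max(rowSums(bv))
    list(reference = ref, shifts = best[ref, ])
  }
  withr::with_seed(10, {
    D <- matrix(rnorm(1500 * 4), ncol = 4)
    D[, 2] <- c(D[-(1:3), 1], rnorm(3))       # correlated, shifted copies
    D[, 3] <- c(rnorm(5), D[1:(1500 - 5), 1])
  })
  L <- 8
  plan <- estimate_channel_delays(D, max_lag_ms = L / fs * 1000,
                                  sampling_rate = fs)
  oracle <- brute_plan(D, L)
  expect_identical(plan$reference, as.integer(oracle$reference))
  expect_identical(as.integer(plan$shifts), as.integer(oracle$shifts))
})

test_that("identical channels give zero shifts and the lowest reference", {
  x <- sine(500, 3000)
  D <- cbind(x, x, x)
  plan <- estimate_channel_delays(D, max_lag_ms = 1, sampling_rate = fs)
  expect_identical(as.integer(plan$shifts), c(0L, 0L, 0L))
  expect_identical(plan$reference, 1L)
})

test_that("delay estimation is equivariant to a common shift", {
  withr::with_seed(11, {
    n <- 6000
    base <- as.numeric(stats::filter(rnorm(n + 300), rep(1, 7), sides = 2))
    base[is.na(base)] <- 0
    s1 <- c(0L, 7L, -9L)
    D1 <- vapply(s1, function(s) base[seq_len(n) + 150 - s], numeric(n))
    D2 <- vapply(s1 + 4L, function(s) base[seq_len(n) + 150 - s], numeric(n))
  })
  p1 <- estimate_channel_delays(D1, max_lag_ms = 1, sampling_rate = fs)
  p2 <- estimate_channel_delays(D2, max_lag_ms = 1, sampling_rate = fs)
  expect_identical(p1$shifts - p1$shifts[1], p2$shifts - p2$shifts[1])
})

test_that("applying delays rolls channels and zero-fills the edges", {
  D <- matrix(seq_len(40), ncol = 2)
  expect_identical(apply_channel_delays(D, c(0L, 0L)), D * 1)
  rolled <- apply_channel_delays(D, c(3L, -2L))
  back <- apply_channel_delays(rolled, c(-3L, 2L))
  inner <- 4:17
  expect_equal(back[inner, ], D[inner, ] * 1)
  expect_equal(rolled[1:17, 1], D[4:20, 1] * 1)
  expect_equal(rolled[18:20, 1], c(0, 0, 0))
  expect_error(apply_channel_delays(D, c(50L, 0L)), "length")
})

test_that("the dense linear channel map has uniform 2 um spacing", {
  expect_equal(make_channel_map(1)$position_um, 0)
  m8 <- make_channel_map(8)
  expect_equal(unique(diff(m8$position_um)), 2)
  expect_equal(m8$position_um[8], 14)         # (n - 1) * 2
})

test_that("delay plans round trip through JSON", {
  withr::with_seed(12, D <- matrix(rnorm(4000 * 3), ncol = 3))
  plan <- estimate_channel_delays(D, max_lag_ms = 0.5, sampling_rate = fs)
  path <- withr::local_tempfile(fileext = ".json")
  write_delay_plan(plan, path)
  p2 <- read_delay_plan(path)
  expect_identical(p2$reference, plan$reference)
  expect_identical(p2$shifts, as.integer(plan$shifts))
  expect_identical(p2$max_lag, as.integer(plan$max_lag))
})
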