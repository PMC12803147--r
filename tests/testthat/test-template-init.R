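# Template initialization: crossings, outlier rejection, PCs, K-means,
# convolutional detection.

gabor_shape <- function(nt = 61, f = 1 / 15, c0 = 20, w = 8, phase = 0) {
  s <- sin(2 * pi * f * (seq_len(nt) - c0) + phase) *
    exp(-((seq_len(nt) - c0)^2) / (2 * w^2))
  s / max(abs(s))
}

test_that("no crossings are found below the lowest threshold", {
  D <- withr::with_seed(1, matrix(rnorm(30000 * 3, sd = 0.5), ncol = 3))
  expect_warning(
    ws <- extract_nonoverlapping_crossings(D, thresholds = c(6, 9), nt = 61,
                                           sampling_rate = 30000),
    "no isolated"
  )
  expect_identical(nrow(ws$waveforms), 0L)
})

test_that("crossings violating the isolation region are excluded", {
  withr::with_seed(2, {
    D <- matrix(rnorm(30000 * 2, sd = 0.5), ncol = 2)
    # cosine phase, narrow envelope: a single dominant lobe, so each
    # planted spike yields exactly one threshold-crossing event
    shape <- gabor_shape(61, f = 1 / 24, c0 = 20, w = 6, phase = pi / 2)
    # two spikes 0.5 ms apart on one channel: both must go
    for (tt in c(9000, 9015)) D[tt + 0:60 - 20, 1] <- D[tt + 0:60 - 20, 1] + 12 * shape
    # an isolated spike elsewhere survives
    D[20000 + 0:60 - 20, 2] <- D[20000 + 0:60 - 20, 2] + 12 * shape
  })
  ws <- extract_nonoverlapping_crossings(D, thresholds = 6, nt = 61, nskip = 1,
                                         sampling_rate = 30000)
  expect_identical(unique(ws$channel), 2L)
  expect_identical(nrow(ws$waveforms), 1L)
  # oracle: the two planted crossings on channel 1 are 15 samples apart,
  # inside the 30-sample isolation radius
  expect_lt(15, 30)
})

test_that("multi-threshold aggregation is a deduplicated union", {
  withr::with_seed(3, {
    D <- matrix(rnorm(60000, sd = 1), ncol = 2)
    shape <- gabor_shape()
    small <- seq(3000, 27000, by = 4000)
    for (tt in small) D[tt + 0:60 - 20, 1] <- D[tt + 0:60 - 20, 1] + 7.5 * shape
    for (tt in small + 2000) D[tt + 0:60 - 20, 2] <- D[tt + 0:60 - 20, 2] + 20 * shape
  })
  lo <- extract_nonoverlapping_crossings(D, thresholds = 6, nt = 61, nskip = 1,
                                         sampling_rate = 30000)
  hi <- extract_nonoverlapping_crossings(D, thresholds = 15, nt = 61, nskip = 1,
                                         sampling_rate = 30000)
  both <- extract_nonoverlapping_crossings(D, thresholds = c(6, 15), nt = 61,
                                           nskip = 1, sampling_rate = 30000)
  key <- function(ws) paste(ws$channel, ws$time)
  expect_true(all(key(hi) %in% key(both)))
  expect_true(all(key(lo) %in% key(both)))
  expect_false(anyDuplicated(key(both)) > 0)
  # batch stride skips every other batch
  strided <- extract_nonoverlapping_crossings(D, thresholds = 6, nt = 61,
                                              nskip = 2, batch_size = 5000,
                                              sampling_rate = 30000)
  expect_lte(nrow(strided$waveforms), nrow(both$waveforms))
  # the large spike at row 9000 sits in an unscanned batch
  expect_false(any(abs(strided$time + 1 - 9000) < 30 & strided$channel == 2))
  expect_true(any(abs(both$time + 1 - 9000) < 30 & both$channel == 2))
})

test_that("density-based outlier rejection removes only sparse points", {
  withr::with_seed(4, {
    X <- rbind(
      matrix(rnorm(200 * 5, 0, 0.1), ncol = 5),
      sweep(matrix(rnorm(200 * 5, 0, 0.1), ncol = 5), 2, c(10, 0, 0, 0, 0), `+`),
      matrix(runif(5 * 5, 40, 80), ncol = 5)
    )
  })
  labels <- hdbscan_labels(X, min_cluster_size = 20)
  expect_true(all(labels[401:405] == 0))            # planted far points
  expect_gte(mean(labels[1:200] != 0), 0.95)
  expect_gte(mean(labels[201:400] != 0), 0.95)
  # homogeneous single cluster: nearly everything retained
  Xh <- withr::with_seed(5, matrix(rnorm(300 * 4), ncol = 4))
  expect_gte(mean(hdbscan_labels(Xh, 20) != 0), 0.90)
})

test_that("outlier rejection never invents waveforms and preserves order", {
  withr::with_seed(6, {
    wf <- rbind(matrix(rnorm(100 * 31, 0, 0.1), ncol = 31) +
                  matrix(rep(gabor_shape(31, c0 = 10), each = 100), ncol = 31),
                matrix(runif(4 * 31, 20, 30), ncol = 31))
  })
  set <- waveform_set(wf, channel = rep(1L, 104), time = seq_len(104) * 100,
                      threshold = rep(6, 104), nt = 31, sampling_rate = 30000)
  out <- reject_outlier_waveforms(set, min_cluster_size = 20)
  expect_lte(nrow(out$waveforms), nrow(set$waveforms))
  idx <- match(out$time, set$time)
  expect_false(is.unsorted(idx))                    # order preserved
  expect_true(all(out$waveforms == set$waveforms[idx, ]))
  # fewer waveforms than the minimum cluster size: unchanged with warning
  small <- waveform_set(wf[1:10, ], rep(1L, 10), seq_len(10) * 100,
                        rep(6, 10), 31, 30000)
  expect_warning(same <- reject_outlier_waveforms(small, 20), "fewer")
  expect_identical(same, small)
})

test_that("temporal components are orthonormal and nested in quality", {
  withr::with_seed(7, {
    shapes <- rbind(gabor_shape(61, 1 / 15), gabor_shape(61, 1 / 9, 25),
                    gabor_shape(61, 1 / 20, 15, 12))
    X <- shapes[sample(1:3, 300, replace = TRUE), ] +
      matrix(rnorm(300 * 61, 0, 0.05), ncol = 61)
  })
  W9 <- compute_temporal_components(X, n_pcs = 9)
  expect_lt(max(abs(tcrossprod(W9) - diag(9))), 1e-8)
  W6 <- compute_temporal_components(X, n_pcs = 6)
  sse <- function(W) sum((X - X %*% t(W) %*% W)^2)   # direct projection oracle
  expect_lte(sse(W9), sse(W6))
  # rank-deficient input pads with a warning
  expect_warning(Wp <- compute_temporal_components(X[rep(1, 20), ], 5), "rank")
  expect_lt(max(abs(tcrossprod(Wp) - diag(5))), 1e-8)
})

test_that("K-means recovers well-separated repeated shapes", {
  withr::with_seed(8, {
    protos <- matrix(rnorm(9 * 61), 9)
    protos <- sweep(protos, 1, apply(abs(protos), 1, max), `/`) * 50
    X <- protos[rep(1:9, each = 30), ]
  })
  tm <- make_simple_templates(X, n_templates = 9, seed = 3)
  norm_protos <- sweep(protos, 1, apply(abs(protos), 1, max), `/`)
  match_err <- vapply(seq_len(9), function(i) {
    min(apply(tm$shapes, 1, function(s) max(abs(s - norm_protos[i, ]))))
  }, numeric(1))
  expect_lt(max(match_err), 1e-6)
  expect_equal(unname(apply(abs(tm$shapes), 1, max)), rep(1, 9))  # peak normalized
  # objective sanity: better than random assignments
  withr::with_seed(9, {
    rand_obj <- replicate(100, {
      lab <- sample.int(9, nrow(X), replace = TRUE)
      sum(vapply(1:9, function(k) {
        xs <- X[lab == k, , drop = FALSE]
        if (nrow(xs) == 0) 0 else sum(sweep(xs, 2, colMeans(xs))^2)
      }, numeric(1)))
    })
  })
  expect_lte(tm$objective, min(rand_obj))
})

test_that("convolutional detection finds a planted spike and nothing in silence", {
  n_ch <- 8
  cm <- make_channel_map(n_ch)
  shape <- gabor_shape()
  tmpl <- matrix(shape, 1)
  expect_identical(nrow(detect_spikes_by_convolution(
    matrix(0, 5000, n_ch), tmpl, cm)), 0L)
  withr::with_seed(10, {
    D <- matrix(rnorm(30000 * n_ch), ncol = n_ch)
    plant <- 15000
    w <- exp(-((1:n_ch) - 4)^2 * 2^2 / (2 * 10^2))
    for (ch in 1:n_ch) D[plant + 0:60 - 20, ch] <- D[plant + 0:60 - 20, ch] +
        25 * w[ch] * shape
  })
  det <- detect_spikes_by_convolution(D, tmpl, cm, Th_universal = 9)
  expect_identical(nrow(det), 1L)
  expect_lte(abs(det$time - (plant - 1)), 1)
  expect_identical(det$channel, 4L)
})

test_that("the initialization chain recovers most spikes of an easy sort", {
  # 5 well-separated units firing sparsely; whiten -> extract -> reject ->
  # templates -> detect; candidate coverage of ground truth >= 90%
  basis <- make_synthetic_basis(n_units = 5, n_channels = 8, nt = 61,
                                n_pcs = 9, max_delay = 6, seed = 21)
  dur <- 8 * 30000
  withr::with_seed(22, {
    trains <- lapply(1:5, function(u) {
      x <- sort(sample.int(dur - 4000, 60)) + 2000
      x[c(TRUE, diff(x) > 900)]
    })
  })
  truth <- spike_trains(rep(1:5, lengths(trains)), unlist(trains), dur, 30000)
  D <- superpose_spikes(dur, truth, basis, seed = 23)
  noise <- fit_noise_levels(D, targets = rep(3, 8), seed = 24)
  w <- whiten(noise$data)
  ws <- extract_nonoverlapping_crossings(w$data, nt = 61, nskip = 1,
                                         sampling_rate = 30000)
  expect_gt(nrow(ws$waveforms), 50)
  ws2 <- reject_outlier_waveforms(ws, 20)
  tm <- make_simple_templates(ws2, n_templates = 5, seed = 25)
  det <- detect_spikes_by_convolution(w$data, tm, make_channel_map(8),
                                      Th_universal = 9)
  tol <- 30                                      # 1 ms
  covered <- vapply(truth$sample_index, function(s) {
    any(abs(det$time - s) <= tol)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
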