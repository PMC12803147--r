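# Evaluation: greedy pairing, alignment, spike matching, metrics,
# overlap restriction, sweep summaries, sorter I/O.

rate <- 30000

test_that("relabeled ground truth is paired back perfectly", {
  truth <- fixture_trains(c(100, 80, 60), duration = rate * 30)
  perm <- c(2L, 3L, 1L)
  sorted <- spike_trains(perm[truth$unit_id], truth$sample_index,
                         rate * 30, rate)
  pairing <- greedy_match_clusters(truth, sorted)
  expect_identical(pairing$cluster, perm)
  expect_equal(pairing$binned_accuracy, rep(1, 3))
})

test_that("empty sorter output leaves all truth units unmatched", {
  truth <- fixture_trains(c(30, 20), duration = rate * 10)
  empty <- spike_trains(integer(0), numeric(0), rate * 10, rate)
  pairing <- greedy_match_clusters(truth, empty)
  expect_true(all(is.na(pairing$cluster)))
  rep <- evaluate_sort(truth, empty)
  expect_equal(rep$A, c(0, 0))
})

test_that("greedy pairing matches exhaustive search on small instances", {
  # independent oracle: exhaustive enumeration of injective assignments,
  # replayed in the same descending-accuracy greedy order
  oracle_pair <- function(truth, sorted, bin_ms = 10) {
    dur_ms <- attr(truth, "duration") / rate * 1000
    tu <- sort(unique(truth$unit_id)); su <- sort(unique(sorted$unit_id))
    acc <- function(t_ms, s_ms) {
      nb <- max(1, ceiling(dur_ms / bin_ms))
      bt <- tabulate(floor(t_ms / bin_ms) + 1, nb)
      bs <- tabulate(floor(s_ms / bin_ms) + 1, nb)
      m <- sum(pmin(bt, bs))
      if (sum(bt) + sum(bs) - m == 0) 0 else m / (sum(bt) + sum(bs) - m)
    }
    A <- outer(seq_along(tu), seq_along(su), Vectorize(function(i, j) {
      acc(truth$sample_index[truth$unit_id == tu[i]] / rate * 1000,
          sorted$sample_index[sorted$unit_id == su[j]] / rate * 1000)
    }))
    assign <- rep(NA_integer_, length(tu))
    repeat {
      k <- which(A == max(A), arr.ind = TRUE)
      if (max(A) == -Inf) break
      k <- k[order(k[, 2], k[, 1]), , drop = FALSE][1, ]  # column-major tie
      assign[k[1]] <- su[k[2]]
      A[k[1], ] <- -Inf; A[, k[2]] <- -Inf
      if (all(!is.na(assign)) || all(A == -Inf)) break
    }
    assign
  }
  for (trial in 1:100) {
    withr::with_seed(1000 + trial, {
      n_t <- sample(2:4, 1); n_s <- sample(1:5, 1)
      dur <- rate * 2
      truth <- spike_trains(rep(seq_len(n_t), each = 15),
                            as.vector(vapply(seq_len(n_t), function(i)
                              sort(sample.int(dur, 15)) - 1, numeric(15))),
                            dur, rate)
      sorted <- spike_trains(rep(seq_len(n_s), each = 12),
                             as.vector(vapply(seq_len(n_s), function(i)
                               sort(sample.int(dur, 12)) - 1, numeric(12))),
                             dur, rate)
    })
    pairing <- greedy_match_clusters(truth, sorted)
    expect_identical(pairing$cluster, oracle_pair(truth, sorted),
                     info = paste("trial", trial))
  }
})

test_that("alignment enumerates 41 candidates and recovers planted delays", {
  t_ms <- withr::with_seed(12, sort(runif(200, 0, 5000)))
  s0 <- align_matched_pair(t_ms, t_ms, 5000)
  expect_identical(as.integer(s0), 0L)
  expect_identical(attr(s0, "n_candidates"), 41L)
  # sorted delayed by +1.5 ms: best shift is -15 bins
  s <- align_matched_pair(t_ms, t_ms + 1.5, 5000)
  expect_identical(as.integer(s), -15L)
  expect_identical(as.integer(align_matched_pair(numeric(0), t_ms, 5000)), 0L)
})

test_that("spike-time matching takes the closest spike once", {
  expect_identical(match_spike_times(numeric(0), numeric(0)),
                   list(n_match = 0L, fp = 0L, fn = 0L))
  t1 <- seq(10, 1000, by = 10)
  m <- match_spike_times(t1, t1)
  expect_identical(m$n_match, length(t1))
  expect_identical(m$fp, 0L)
  # hand-enumerated: one truth spike, two candidates within tolerance
  m2 <- match_spike_times(10.0, c(9.7, 10.4))
  expect_identical(m2$n_match, 1L)
  expect_identical(m2$fp, 1L)
  # jitter within tolerance matches everything
  withr::with_seed(13, jit <- runif(length(t1), -0.9, 0.9))
  m3 <- match_spike_times(t1, t1 + jit)
  expect_identical(m3$n_match, length(t1))
  expect_identical(m3$fp + m3$fn, 0L)
  # a sorted spike cannot serve two truth spikes
  m4 <- match_spike_times(c(10, 10.5), 10.2)
  expect_identical(m4$n_match, 1L)
})

test_that("precision, recall, and accuracy follow the count identities", {
  expect_equal(compute_metrics(10, 10, 10), list(P = 1, R = 1, A = 1))
  expect_equal(compute_metrics(10, 9, 8), list(P = 8 / 9, R = 0.8, A = 8 / 11))
  expect_equal(compute_metrics(10, 9, 0), list(P = 0, R = 0, A = 0))
  expect_equal(compute_metrics(5, 0, 0)$P, 0)     # 0/0 defined as 0
  expect_error(compute_metrics(3, 3, 4), "exceed")
})

test_that("accuracy never exceeds precision or recall", {
  withr::with_seed(14, {
    for (i in 1:200) {
      nt <- sample(0:50, 1); ns <- sample(0:50, 1); nm <- sample(0:min(nt, ns), 1)
      m <- compute_metrics(nt, ns, nm)
      expect_lte(m$A, min(m$P, m$R) + 1e-12)
      if (m$A == 1) expect_true(m$P == 1 && m$R == 1)
    }
  })
})

test_that("ground truth fed back scores perfect accuracy", {
  truth <- fixture_trains(c(200, 150, 100, 60), duration = rate * 60)
  withr::with_seed(15, {
    perm <- sample(4)
    jitter <- round(runif(nrow(truth), -9, 9))     # 0.3 ms dispersion, < 1 ms
    shift <- 45                                    # +1.5 ms global
  })
  sorted <- spike_trains(perm[truth$unit_id],
                         pmin(pmax(truth$sample_index + shift + jitter, 0),
                              rate * 60 - 1),
                         rate * 60, rate)
  rep <- evaluate_sort(truth, sorted)
  expect_equal(rep$A, rep(1, 4))
  expect_equal(rep$P, rep(1, 4))
  expect_identical(rep$matched_cluster, perm[rep$unit])
})

test_that("overlap restriction keeps only cross-unit collisions", {
  dur <- rate * 10
  # single-unit ground truth has no cross-unit neighbours
  one <- fixture_trains(100, duration = dur)
  expect_identical(nrow(select_overlapping_spikes(one, 1)), 0L)
  # constructed 3-unit train with known collisions (times in samples)
  t1 <- c(1000, 5000, 9000)
  t2 <- c(1015, 20000)                             # 1015 collides with 1000 @1ms
  t3 <- c(5055, 40000)                             # 5055 vs 5000: 55 smp > 30
  tr <- spike_trains(c(1, 1, 1, 2, 2, 3, 3), c(t1, t2, t3), dur, rate)
  ov1 <- select_overlapping_spikes(tr, 1)
  # brute-force pairwise enumeration oracle
  brute <- function(win_smp) {
    keep <- vapply(seq_len(nrow(tr)), function(i) {
      any(abs(tr$sample_index - tr$sample_index[i]) <= win_smp &
            tr$unit_id != tr$unit_id[i])
    }, logical(1))
    sort(tr$sample_index[keep])
  }
  expect_identical(sort(ov1$sample_index), brute(30))
  expect_identical(sort(ov1$sample_index), c(1000, 1015))
  ov2 <- select_overlapping_spikes(tr, 2)          # monkey-like window
  expect_identical(sort(ov2$sample_index), brute(60))
  expect_true(all(c(5000, 5055) %in% ov2$sample_index))
})

test_that("overlap-restricted metrics appear alongside the full metrics", {
  dur <- rate * 20
  truth <- fixture_trains(c(150, 150), duration = dur, min_gap = 40)
  sorted <- spike_trains(truth$unit_id, truth$sample_index, dur, rate)
  rep <- evaluate_sort(truth, sorted, overlap_window_ms = 1)
  expect_true(all(c("N_truth_overlap", "A_overlap") %in% names(rep)))
  expect_true(all(rep$A_overlap[rep$N_truth_overlap > 0] == 1))
  g <- glance(rep)
  expect_identical(g$mean_accuracy, 1)
})

test_that("error-rate reduction reproduces the worked arithmetic", {
  expect_equal(round(error_rate_reduction(15.9, 48.9), 1), 67.5)
  expect_equal(round(error_rate_reduction(17.0, 33.9), 1), 49.9)
  expect_equal(error_rate_reduction(5, 5), 0)
  expect_error(error_rate_reduction(1, 0), "positive")
})

test_that("sweep summaries aggregate per-run unit means", {
  s1 <- summarize_sweep(list(c(0.5, 1.0)))
  expect_equal(s1$mean, 0.75)
  expect_equal(s1$sd, 0)
  s3 <- summarize_sweep(list(c(0.9, 0.9), c(0.8, 0.8), c(0.7, 0.7)))
  expect_equal(s3$median, 0.8)
  expect_error(summarize_sweep(list()), "at least one")
  expect_error(summarize_sweep(list(numeric(0))), "empty")
})

test_that("sorter output round trips through Phy-style and CSV formats", {
  tr <- fixture_trains(c(40, 30), duration = rate * 5)
  dir <- withr::local_tempdir()
  write_sorter_output(tr, dir)
  tr2 <- read_sorter_output(dir, duration = rate * 5)
  expect_equal(tr2$unit_id, tr$unit_id)
  expect_equal(tr2$sample_index, tr$sample_index)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cluster_id = tr$unit_id,
                              sample_index = tr$sample_index),
                   csv, row.names = FALSE)
  tr3 <- read_sorter_output(csv, duration = rate * 5)
  expect_equal(tr3$sample_index, tr$sample_index)
})

test_that("match reports serialize to JSON and CSV", {
  truth <- fixture_trains(c(30, 20), duration = rate * 10)
  rep <- evaluate_sort(truth, truth)
  prefix <- file.path(withr::local_tempdir(), "report")
  write_match_report(rep, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(j$units$A, rep$A)
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(csv$N_match, rep$N_match)
})
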