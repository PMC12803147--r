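# Ground-truth evaluation: three-stage matching of sorted clusters to
# truth units (coarse greedy pairing -> fine alignment -> spike-time
# matching), then precision/recall/accuracy per unit.

bin_spike_counts <- function(times_ms, bin_ms, n_bins) {
  idx <- floor(times_ms / bin_ms) + 1L
  tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
}

# Binned accuracy used by stage 1: per-bin matched count is
# min(truth, sort); A = match / (truth + sort - match) over summed counts.
binned_accuracy <- function(truth_ms, sort_ms, bin_ms, total_ms) {
  n_bins <- max(1L, ceiling(total_ms / bin_ms))
  ct <- bin_spike_counts(truth_ms, bin_ms, n_bins)
  cs <- bin_spike_counts(sort_ms, bin_ms, n_bins)
  m <- sum(pmin(ct, cs))
  den <- sum(ct) + sum(cs) - m
  if (den == 0) 0 else m / den
}

#' Stage 1: greedy cluster-to-unit pairing
#'
#' Bins both spike sets at `bin_ms` (10 ms) and pairs sorted clusters to
#' ground-truth units without replacement, in descending order of the
#' binned accuracy, until either side is exhausted. Unmatched truth units
#' score 0.
#'
#' @param truth,sorted [spike_trains()] tibbles (truth must be non-empty).
#' @param bin_ms Coarse bin width in ms.
#' @return Tibble `truth_unit`, `cluster` (NA when unmatched),
#'   `binned_accuracy`.
#' @export
greedy_match_clusters <- function(truth, sorted, bin_ms = 10) {
  rate <- train_rate(truth)
  total_ms <- train_duration(truth) / rate * 1000
  t_units <- sort(unique(truth$unit_id))
  s_units <- sort(unique(sorted$unit_id))
  if (length(t_units) == 0L) stop("at least one truth unit required")
  tt <- lapply(split(truth$sample_index, truth$unit_id), function(x) x / rate * 1000)
  st <- lapply(split(sorted$sample_index, sorted$unit_id),
               function(x) x / train_rate(sorted) * 1000)
  A <- matrix(0, length(t_units), length(s_units))
  for (i in seq_along(t_units)) {
    for (j in seq_along(s_units)) {
      A[i, j] <- binned_accuracy(tt[[as.character(t_units[i])]],
                                 st[[as.character(s_units[j])]],
                                 bin_ms, total_ms)
    }
  }
  pairing <- tibble::tibble(truth_unit = t_units,
                            cluster = rep(NA_integer_, length(t_units)),
                            binned_accuracy = 0)
  if (length(s_units)) {
    Awork <- A
    for (step in seq_len(min(length(t_units), length(s_units)))) {
      k <- which.max(Awork)                   # first (column-major) max wins ties
      i <- (k - 1L) %% nrow(Awork) + 1L
      j <- (k - 1L) %/% nrow(Awork) + 1L
      pairing$cluster[i] <- s_units[j]
      pairing$binned_accuracy[i] <- A[i, j]
      Awork[i, ] <- -Inf
      Awork[, j] <- -Inf
    }
  }
  pairing
}

#' Stage 2: fine alignment of a matched pair
#'
#' Bins both trains at `bin_ms` (0.1 ms) and evaluates exactly
#' `2 * max_shift_bins + 1` (41) shifted copies of the sorted train
#' between `-max_shift_bins` and `+max_shift_bins` bins, returning the
#' shift (in bins, to be *added* to the sorted times) that maximizes the
#' Pearson correlation with the truth-binned counts. Ties break toward
#' `|shift| = 0`, then toward the negative shift.
#'
#' @param truth_ms,sort_ms Spike times in ms.
#' @param total_ms Recording length in ms.
#' @param bin_ms Fine bin width (0.1 ms).
#' @param max_shift_bins Half-range of candidate shifts (20).
#' @return Integer best shift in bins; 0 for an empty train. The number
#'   of evaluated candidates is attached as attribute `n_candidates`.
#' @export
align_matched_pair <- function(truth_ms, sort_ms, total_ms, bin_ms = 0.1,
                               max_shift_bins = 20) {
  shifts <- -max_shift_bins:max_shift_bins
  if (length(truth_ms) == 0L || length(sort_ms) == 0L) {
    return(structure(0L, n_candidates = length(shifts)))
  }
  n_bins <- max(1L, ceiling(total_ms / bin_ms)) + max_shift_bins
  bt <- bin_spike_counts(truth_ms, bin_ms, n_bins)
  cors <- vapply(shifts, function(s) {
    bs <- bin_spike_counts(sort_ms + s * bin_ms, bin_ms, n_bins)
    if (stats::sd(bs) == 0 || stats::sd(bt) == 0) return(-Inf)
    stats::cor(bt, bs)
  }, numeric(1))
  pref <- order(abs(shifts), shifts)           # |shift| small first, then negative
  best <- pref[which.max(cors[pref])]
  structure(shifts[best], n_candidates = length(shifts))
}

#' Stage 3: one-to-one spike-time matching
#'
#' Each truth spike may claim at most one sorted spike within
#' `+/- tol_ms`; when several sorted spikes qualify only the closest
#' counts as a true positive and the rest remain available (ultimately
#' false positives), and no sorted spike serves two truth spikes.
#' Contention is resolved greedily by ascending `|dt|`.
#'
#' @param truth_ms,sort_ms Sorted spike times in ms (alignment already
#'   applied to `sort_ms`).
#' @param tol_ms Matching tolerance (1 ms).
#' @return List with `n_match`, `fp`, `fn`.
#' @export
match_spike_times <- function(truth_ms, sort_ms, tol_ms = 1) {
  nt <- length(truth_ms); ns <- length(sort_ms)
  if (nt == 0L || ns == 0L) return(list(n_match = 0L, fp = ns, fn = nt))
  truth_ms <- sort(truth_ms); sort_ms <- sort(sort_ms)
  # candidate pairs within tolerance
  lo <- findInterval(truth_ms - tol_ms, sort_ms) + 1L
  hi <- findInterval(truth_ms + tol_ms, sort_ms)
  ti <- rep.int(seq_len(nt), pmax(hi - lo + 1L, 0L))
  si <- unlist(lapply(seq_len(nt), function(i) {
    if (hi[i] >= lo[i]) lo[i]:hi[i] else integer(0)
  }), use.names = FALSE)
  if (!length(ti)) return(list(n_match = 0L, fp = ns, fn = nt))
  dt <- abs(truth_ms[ti] - sort_ms[si])
  ord <- order(dt)
  used_t <- logical(nt); used_s <- logical(ns)
  n_match <- 0L
  for (k in ord) {
    if (!used_t[ti[k]] && !used_s[si[k]]) {
      used_t[ti[k]] <- TRUE
      used_s[si[k]] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(n_match = n_match, fp = ns - n_match, fn = nt - n_match)
}

#' Precision, recall, and accuracy from match counts
#'
#' `P = N_match / N_sort`, `R = N_match / N_truth`,
#' `A = N_match / (N_truth + N_sort - N_match)`; `0/0` is defined as 0.
#'
#' @param n_truth,n_sort,n_match Spike counts
#'   (`n_match <= min(n_truth, n_sort)`).
#' @return Named list `P`, `R`, `A`.
#' @export
compute_metrics <- function(n_truth, n_sort, n_match) {
  if (n_match > min(n_truth, n_sort)) {
    stop("n_match cannot exceed min(n_truth, n_sort)")
  }
  div0 <- function(a, b) if (b == 0) 0 else a / b
  list(P = div0(n_match, n_sort),
       R = div0(n_match, n_truth),
       A = div0(n_match, n_truth + n_sort - n_match))
}

#' Restrict ground truth to overlap-affected spikes
#'
#' Keeps each truth spike that has at least one spike from a *different*
#' unit within `+/- overlap_window_ms` (half the template window: 1 ms
#' for rat-like, 2 ms for monkey-like recordings), the regime in which
#' waveforms superpose and sorting is hardest.
#'
#' @param truth A [spike_trains()] tibble.
#' @param overlap_window_ms Overlap window in ms (> 0).
#' @return The subsetted `spike_trains` (may be empty).
#' @export
select_overlapping_spikes <- function(truth, overlap_window_ms) {
  if (overlap_window_ms <= 0) stop("overlap window must be positive")
  rate <- train_rate(truth)
  win <- overlap_window_ms / 1000 * rate       # samples
  keep <- vapply(seq_len(nrow(truth)), function(i) {
    other <- truth$unit_id != truth$unit_id[i]
    any(abs(truth$sample_index[other] - truth$sample_index[i]) <= win)
  }, logical(1))
  out <- truth[keep, ]
  structure(out, duration = train_duration(truth), sampling_rate = rate,
            class = class(truth))
}

#' Evaluate a sort against ground truth
#'
#' Runs the full three-stage procedure and reports per-truth-unit counts
#' and metrics, plus overlap-restricted counterparts when
#' `overlap_window_ms` is given (both sides restricted: truth spikes to
#' the overlap subset, sorted spikes to those attributable to it within
#' the matching tolerance).
#'
#' @param truth,sorted [spike_trains()] tibbles.
#' @param tol_ms Stage-3 matching tolerance in ms.
#' @param overlap_window_ms Optional overlap window in ms.
#' @param bin_ms,fine_bin_ms Stage-1 and stage-2 bin widths in ms.
#' @return A `match_report`: tibble with one row per truth unit (`unit`,
#'   `matched_cluster`, `shift_bins`, `N_truth`, `N_sort`, `N_match`,
#'   `P`, `R`, `A`, and `*_overlap` columns when requested).
#' @export
evaluate_sort <- function(truth, sorted, tol_ms = 1, overlap_window_ms = NULL,
                          bin_ms = 10, fine_bin_ms = 0.1) {
  rate <- train_rate(truth)
  total_ms <- train_duration(truth) / rate * 1000
  pairing <- greedy_match_clusters(truth, sorted, bin_ms = bin_ms)
  tt <- split(truth$sample_index / rate * 1000, truth$unit_id)
  st <- split(sorted$sample_index / train_rate(sorted) * 1000, sorted$unit_id)
  overlap <- if (!is.null(overlap_window_ms)) {
    ov <- select_overlapping_spikes(truth, overlap_window_ms)
    split(ov$sample_index / rate * 1000, factor(ov$unit_id,
                                                levels = pairing$truth_unit))
  } else NULL

  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    u <- pairing$truth_unit[i]
    cl <- pairing$cluster[i]
    t_ms <- tt[[as.character(u)]]
    s_ms <- if (!is.na(cl)) st[[as.character(cl)]] else numeric(0)
    shift <- align_matched_pair(t_ms, s_ms, total_ms, bin_ms = fine_bin_ms)
    s_al <- s_ms + as.integer(shift) * fine_bin_ms
    mm <- match_spike_times(t_ms, s_al, tol_ms = tol_ms)
    met <- compute_metrics(length(t_ms), length(s_al), mm$n_match)
    row <- tibble::tibble(
      unit = u, matched_cluster = cl, shift_bins = as.integer(shift),
      N_truth = length(t_ms), N_sort = length(s_al), N_match = mm$n_match,
      P = met$P, R = met$R, A = met$A
    )
    if (!is.null(overlap)) {
      t_ov <- overlap[[as.character(u)]] %||% numeric(0)
      s_ov <- if (length(t_ov)) {
        near <- vapply(s_al, function(s) any(abs(t_ov - s) <= tol_ms), logical(1))
        s_al[near]
      } else numeric(0)
      mo <- match_spike_times(t_ov, s_ov, tol_ms = tol_ms)
      meto <- compute_metrics(length(t_ov), length(s_ov), mo$n_match)
      row$N_truth_overlap <- length(t_ov)
      row$N_sort_overlap <- length(s_ov)
      row$N_match_overlap <- mo$n_match
      row$P_overlap <- meto$P
      row$R_overlap <- meto$R
      row$A_overlap <- meto$A
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  structure(out, tol_ms = tol_ms, overlap_window_ms = overlap_window_ms,
            class = c("match_report", class(out)))
}

#' Percent reduction in error rate
#'
#' `100 * (1 - e_new / e_ref)`: the share of reference errors removed.
#'
#' @param e_new,e_ref New and reference error rates (`e_ref > 0`).
#' @return Percent reduction (negative when `e_new > e_ref`).
#' @export
error_rate_reduction <- function(e_new, e_ref) {
  if (e_ref <= 0) stop("reference error rate must be positive")
  100 * (1 - e_new / e_ref)
}

#' Summarize accuracies across sweep runs
#'
#' Each run contributes the mean accuracy across its units; the summary
#' reports the median, mean, and SD of those per-run means (SD of a
#' single run is 0).
#'
#' @param runs List of per-run numeric vectors of per-unit accuracies.
#' @return Tibble with `n_runs`, `median`, `mean`, `sd`.
#' @export
summarize_sweep <- function(runs) {
  if (length(runs) < 1L) stop("at least one run required")
  means <- vapply(runs, function(a) {
    if (length(a) == 0L) stop("run with empty unit accuracy list")
    mean(a)
  }, numeric(1))
  tibble::tibble(
    n_runs = length(means),
    median = stats::median(means),
    mean = mean(means),
    sd = if (length(means) > 1L) stats::sd(means) else 0
  )
}

#' Read or write a Phy-style sorter output
#'
#' A Phy-style directory holds `spike_times.npy` (int64 sample indices)
#' and `spike_clusters.npy` (int32 labels); the CSV alternative is a
#' single file with header `cluster_id,sample_index`.
#'
#' @param path Directory (Phy style) or CSV file path.
#' @param duration,sampling_rate Recording length (samples) and rate.
#' @return A [spike_trains()] tibble with clusters as `unit_id`.
#' @export
read_sorter_output <- function(path, duration = NULL, sampling_rate = 30000) {
  if (dir.exists(path)) {
    times <- as.numeric(read_npy(file.path(path, "spike_times.npy")))
    clusters <- as.integer(read_npy(file.path(path, "spike_clusters.npy")))
  } else {
    df <- utils::read.csv(path)
    if (!all(c("cluster_id", "sample_index") %in% names(df))) {
      stop("sorter CSV must have columns cluster_id,sample_index")
    }
    times <- df$sample_index
    clusters <- df$cluster_id
  }
  spike_trains(clusters, times,
               duration = duration %||% (max(times) + 1),
               sampling_rate = sampling_rate)
}

#' @rdname read_sorter_output
#' @param x A [spike_trains()] tibble.
#' @export
write_sorter_output <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_npy(x$sample_index, file.path(path, "spike_times.npy"), "int64")
  write_npy(x$unit_id, file.path(path, "spike_clusters.npy"), "int32")
  invisible(path)
}

#' Match-report serialization
#'
#' Writes the report as JSON and as a per-unit CSV.
#'
#' @param report A `match_report`.
#' @param prefix Output path prefix (`<prefix>.json`, `<prefix>.csv`).
#' @export
write_match_report <- function(report, prefix) {
  jsonlite::write_json(
    list(tol_ms = attr(report, "tol_ms"),
         overlap_window_ms = attr(report, "overlap_window_ms"),
         units = as.data.frame(report)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  utils::write.csv(as.data.frame(report), paste0(prefix, ".csv"),
                   row.names = FALSE)
  invisible(prefix)
}
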