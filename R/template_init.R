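#' Waveform sets
#'
#' Single-channel spike snippets harvested from a whitened recording:
#' a matrix of waveforms (`n_spikes x nt`, peak aligned at sample
#' `floor(nt/3)`) plus, per spike, the channel and 0-based sample of
#' origin and the threshold that found it.
#'
#' @param waveforms Matrix `n_spikes x nt`.
#' @param channel,time,threshold Per-spike provenance vectors.
#' @param nt Window length in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `waveform_set`.
#' @export
waveform_set <- function(waveforms, channel, time, threshold, nt,
                         sampling_rate) {
  stopifnot(nrow(waveforms) == length(channel),
            length(channel) == length(time))
  if (anyDuplicated(cbind(channel, time))) {
    stop("duplicate (channel, time) waveform entries")
  }
  structure(list(waveforms = waveforms, channel = as.integer(channel),
                 time = as.numeric(time), threshold = as.numeric(threshold),
                 nt = as.integer(nt), sampling_rate = sampling_rate),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d waveforms of %d samples from %d channels\n",
              nrow(x$waveforms), x$nt, length(unique(x$channel))))
  invisible(x)
}

# Threshold-crossing events on one channel: local maxima of |x| above
# `th`, with non-maximum suppression over +/-`radius` samples so the
# several lobes of one multiphasic waveform collapse to a single event
# (two distinct spikes further apart than the radius stay separate).
threshold_peaks <- function(x, th, radius = 8L) {
  a <- abs(x)
  cand <- which(a > th)
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - radius); hi <- min(length(a), i + radius)
    w <- a[lo:hi]
    m <- max(w)
    a[i] == m && i == (lo + which.max(w) - 1L)   # first index wins plateaus
  }, logical(1))
  cand[keep]
}

#' Extract time-isolated threshold crossings
#'
#' For each detection threshold (in units of variance, i.e. on whitened
#' data), finds absolute-value crossing peaks per channel and keeps only
#' crossings with no other crossing within +/-`isolation_ms` on the same
#' or the `isolation_chans` neighbouring channels on either side. Results
#' are aggregated across all thresholds with duplicate `(channel, time)`
#' entries removed and near-duplicates (within +/-0.2 ms) collapsed to
#' the largest-amplitude instance. Data are scanned in batches of
#' `batch_size` samples, visiting only every `nskip`-th batch.
#'
#' @param D_white Whitened data matrix `time x channels`.
#' @param thresholds Ascending detection thresholds; default
#'   `c(6, 9, 12, 15)`.
#' @param nt Waveform window length (samples).
#' @param nskip Batch stride (scan every `nskip`-th batch).
#' @param batch_size Batch length in samples.
#' @param isolation_ms,isolation_chans Time and channel isolation radii.
#' @param sampling_rate Sampling rate in Hz.
#' @return A [waveform_set()]; empty (with a warning) when nothing
#'   crosses the lowest threshold.
#' @export
extract_nonoverlapping_crossings <- function(D_white,
                                             thresholds = c(6, 9, 12, 15),
                                             nt = 61, nskip = 2,
                                             batch_size = 60000,
                                             isolation_ms = 1,
                                             isolation_chans = 6,
                                             sampling_rate = 30000) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  n <- nrow(D_white); n_ch <- ncol(D_white)
  iso_n <- round(isolation_ms / 1000 * sampling_rate)
  peak_radius <- max(2L, round(0.25e-3 * sampling_rate))
  off <- spike_center_offset(nt)
  batch_starts <- seq(1L, n, by = batch_size)
  scanned <- batch_starts[seq(1L, length(batch_starts), by = nskip)]

  found <- list()
  for (b0 in scanned) {
    b1 <- min(b0 + batch_size - 1L, n)
    for (th in thresholds) {
      cand_t <- integer(0); cand_c <- integer(0)
      for (ch in seq_len(n_ch)) {
        pk <- threshold_peaks(D_white[b0:b1, ch], th, radius = peak_radius)
        cand_t <- c(cand_t, pk + b0 - 1L)
        cand_c <- c(cand_c, rep(ch, length(pk)))
      }
      if (!length(cand_t)) next
      keep <- vapply(seq_along(cand_t), function(i) {
        near <- abs(cand_t - cand_t[i]) <= iso_n &
          abs(cand_c - cand_c[i]) <= isolation_chans
        sum(near) == 1L                       # only itself
      }, logical(1))
      if (any(keep)) {
        found[[length(found) + 1L]] <- tibble::tibble(
          time = cand_t[keep], channel = cand_c[keep], threshold = th
        )
      }
    }
  }
  if (!length(found)) {
    warning("no isolated threshold crossings found")
    return(waveform_set(matrix(0, 0, nt), integer(0), numeric(0), numeric(0),
                        nt, sampling_rate))
  }
  all_cr <- dplyr::bind_rows(found)
  all_cr$amp <- abs(D_white[cbind(all_cr$time, all_cr$channel)])
  # exact duplicates: keep the one found at the lowest threshold
  all_cr <- dplyr::slice_min(dplyr::group_by(all_cr, .data$channel, .data$time),
                             .data$threshold, n = 1, with_ties = FALSE)
  all_cr <- dplyr::ungroup(all_cr)
  # near-duplicates within +/-0.2 ms on the same channel: keep the largest
  near_n <- round(0.2e-3 * sampling_rate)
  all_cr <- dplyr::arrange(all_cr, .data$channel, .data$time)
  keep <- rep(TRUE, nrow(all_cr))
  for (i in seq_len(nrow(all_cr))) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= nrow(all_cr) && all_cr$channel[j] == all_cr$channel[i] &&
           all_cr$time[j] - all_cr$time[i] <= near_n) {
      if (all_cr$amp[j] > all_cr$amp[i]) keep[i] <- FALSE else keep[j] <- FALSE
      j <- j + 1L
    }
  }
  all_cr <- all_cr[keep, ]
  # full-window constraint (1-based rows: time - off .. time - off + nt - 1)
  ok <- all_cr$time - off >= 1L & all_cr$time - off + nt - 1L <= n
  all_cr <- all_cr[ok, ]
  wf <- matrix(0, nrow(all_cr), nt)
  for (i in seq_len(nrow(all_cr))) {
    wf[i, ] <- D_white[all_cr$time[i] - off + 0:(nt - 1L), all_cr$channel[i]]
  }
  waveform_set(wf, all_cr$channel, all_cr$time - 1L, all_cr$threshold,
               nt, sampling_rate)
}

#' Reject outlier waveforms by density clustering
#'
#' Runs [hdbscan_labels()] on the raw `nt`-sample waveform vectors
#' (Euclidean distance in the full feature space) and removes waveforms
#' labelled noise; survivors keep their original order. Never invents
#' waveforms: the output is a subset of the input.
#'
#' @param set A [waveform_set()].
#' @param min_cluster_size HDBSCAN minimum cluster size (default 20).
#' @return The filtered `waveform_set`.
#' @export
reject_outlier_waveforms <- function(set, min_cluster_size = 20) {
  n <- nrow(set$waveforms)
  if (n == 0L) stop("empty waveform set")
  if (n < min_cluster_size) {
    warning("fewer waveforms than min_cluster_size; returning input unchanged")
    return(set)
  }
  labels <- hdbscan_labels(set$waveforms, min_cluster_size = min_cluster_size)
  keep <- labels != 0L
  waveform_set(set$waveforms[keep, , drop = FALSE], set$channel[keep],
               set$time[keep], set$threshold[keep], set$nt, set$sampling_rate)
}

#' Principal-component temporal basis of a waveform set
#'
#' The top `n_pcs` principal axes (uncentred SVD) of the waveform matrix,
#' orthonormal and ordered by explained variance. If the matrix rank is
#' below `n_pcs` the basis is padded with an orthogonal complement, with
#' a warning.
#'
#' @param set A [waveform_set()] (or bare waveform matrix).
#' @param n_pcs Number of components (default 9).
#' @return Matrix `n_pcs x nt` with orthonormal rows.
#' @export
compute_temporal_components <- function(set, n_pcs = 9) {
  X <- if (inherits(set, "waveform_set")) set$waveforms else set
  if (nrow(X) < n_pcs) stop("need at least n_pcs waveforms")
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(n_pcs, rank)
  W <- t(sv$v[, seq_len(k), drop = FALSE])
  if (k < n_pcs) {
    warning("waveform matrix rank ", rank, " < n_pcs; padding basis")
    nt <- ncol(X)
    Q <- qr.Q(qr(cbind(t(W), diag(nt)[, seq_len(nt)])))
    W <- t(Q[, seq_len(n_pcs), drop = FALSE])
  }
  W
}

# k-means++ seeding
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1], ])^2)
  for (i in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = p)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[i + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Cluster waveforms into simple templates
#'
#' K-means (k-means++ initialization, 10 restarts, fixed seed) on the
#' waveform vectors; the template shapes are the cluster centres, each
#' peak-normalized to unit absolute maximum.
#'
#' @param set A [waveform_set()] (or bare waveform matrix).
#' @param n_templates Number of templates (default 9).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts.
#' @return A `simple_templates`: `shapes` (`n_templates x nt`, peak
#'   normalized), `objective` (within-cluster SSE), `cluster` labels.
#' @export
make_simple_templates <- function(set, n_templates = 9, seed = 1,
                                  restarts = 10) {
  X <- if (inherits(set, "waveform_set")) set$waveforms else set
  if (nrow(X) < n_templates) stop("need at least n_templates waveforms")
  best <- NULL
  with_seed(substream_seed(seed, "kmeans"), {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_centers(X, n_templates)
      init <- init + matrix(stats::rnorm(length(init), sd = 1e-9), nrow(init))
      fit <- tryCatch(
        stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100,
                                         algorithm = "Lloyd"))
        }
      )
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop("k-means failed on the waveform set")
  shapes <- best$centers
  peaks <- apply(abs(shapes), 1L, max)
  shapes <- sweep(shapes, 1L, pmax(peaks, .Machine$double.eps), `/`)
  structure(list(shapes = shapes, objective = best$tot.withinss,
                 cluster = best$cluster, n_templates = as.integer(n_templates),
                 seed = as.integer(seed)),
            class = "simple_templates")
}

#' Convolutional spike detection with simple templates
#'
#' Each template shape is replicated across channels with a Gaussian
#' spatial decay centred on every channel, at each candidate spatial size
#' (`1..template_sizes` multiples of `min_template_size` micrometres; the
#' Gaussian SD equals the size). The unit-norm spatiotemporal kernels are
#' correlated with the whitened data; scores above `Th_universal`
#' (variance units) that are local maxima over time (+/- half a window)
#' and the `nearest_chans` neighbouring channels become candidate spikes,
#' keeping the best template and size per detection.
#'
#' @param D_white Whitened data matrix `time x channels`.
#' @param templates A `simple_templates` (or bare shape matrix).
#' @param channel_map A [make_channel_map()] tibble.
#' @param Th_universal Detection threshold (default 9).
#' @param min_template_size Smallest spatial size in micrometres.
#' @param template_sizes Number of size multiples to try.
#' @param nearest_chans Channels participating in local-maximum
#'   suppression.
#' @return Tibble of detections: `time` (0-based sample), `channel`,
#'   `template`, `size_um`, `score`.
#' @export
detect_spikes_by_convolution <- function(D_white, templates, channel_map,
                                         Th_universal = 9,
                                         min_template_size = 10,
                                         template_sizes = 5,
                                         nearest_chans = 10) {
  shapes <- if (inherits(templates, "simple_templates")) templates$shapes
            else templates
  n <- nrow(D_white); n_ch <- ncol(D_white)
  nt <- ncol(shapes)
  off <- spike_center_offset(nt)
  pos <- channel_map$position_um
  stopifnot(length(pos) == n_ch)
  sizes <- seq_len(template_sizes) * min_template_size

  # spatial weight matrices [n_ch x n_ch] per size (column = center channel)
  Wsp <- lapply(sizes, function(s) {
    M <- exp(-outer(pos, pos, `-`)^2 / (2 * s^2))
    # keep only the nearest channels, unit-norm columns
    for (c0 in seq_len(n_ch)) {
      ord <- order(abs(pos - pos[c0]))
      M[ord[-seq_len(min(nearest_chans, n_ch))], c0] <- 0
      M[, c0] <- M[, c0] / sqrt(sum(M[, c0]^2))
    }
    M
  })

  best_score <- matrix(-Inf, n, n_ch)
  best_tmpl <- matrix(0L, n, n_ch)
  best_size <- matrix(0L, n, n_ch)
  for (k in seq_len(nrow(shapes))) {
    shape <- shapes[k, ]
    shape <- shape / sqrt(sum(shape^2))
    # CC[t, c]: correlation of the shape with channel c, spike at window
    # sample off+1 aligned to t
    CC <- apply(D_white, 2L, function(x) {
      full <- stats::convolve(x, shape, type = "open")  # length n + nt - 1
      full[(nt - off):(nt - off + n - 1L)]
    })
    for (si in seq_along(sizes)) {
      sc <- abs(CC %*% Wsp[[si]])
      upd <- sc > best_score
      best_score[upd] <- sc[upd]
      best_tmpl[upd] <- k
      best_size[upd] <- si
    }
  }

  hits <- which(best_score > Th_universal, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(tibble::tibble(time = numeric(0), channel = integer(0),
                          template = integer(0), size_um = numeric(0),
                          score = numeric(0)))
  }
  half <- nt %/% 2
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    t0 <- hits[i, 1]; c0 <- hits[i, 2]
    trange <- max(1L, t0 - half):min(n, t0 + half)
    ord <- order(abs(pos - pos[c0]))
    nb <- ord[seq_len(min(nearest_chans, n_ch))]
    keep[i] <- best_score[t0, c0] >= max(best_score[trange, nb])
  }
  hits <- hits[keep, , drop = FALSE]
  tibble::tibble(
    time = hits[, 1] - 1,                       # 0-based
    channel = as.integer(hits[, 2]),
    template = best_tmpl[hits],
    size_um = sizes[best_size[hits]],
    score = best_score[hits]
  )
}
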