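# ggplot2 views of the main result types.

#' Plot a few seconds of a simulated recording
#'
#' Stacked channel traces with ground-truth spike times ticked underneath.
#'
#' @param object A `muap_recording`.
#' @param t_start,t_end Window in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot muap_recording
#' @export
autoplot.muap_recording <- function(object, t_start = 0,
                                    t_end = min(2, nrow(object$data) /
                                                  object$sampling_rate), ...) {
  rate <- object$sampling_rate
  rows <- max(1L, floor(t_start * rate) + 1L):min(nrow(object$data),
                                                  ceiling(t_end * rate))
  spread <- max(apply(object$data[rows, , drop = FALSE], 2L, stats::sd)) * 6
  df <- tibble::tibble(
    t = rep(rows / rate, ncol(object$data)),
    channel = rep(seq_len(ncol(object$data)), each = length(rows)),
    v = as.vector(object$data[rows, ])
  )
  gt <- dplyr::filter(
    tibble::as_tibble(object$ground_truth),
    .data$sample_index / rate >= t_start, .data$sample_index / rate <= t_end
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$v + .data$channel * spread,
                                   group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_point(
      data = gt,
      ggplot2::aes(x = .data$sample_index / rate,
                   y = -spread / 2 - .data$unit_id * spread / 8),
      inherit.aes = FALSE, shape = 3, size = 0.8,
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "time (s)", y = "channel (offset traces)",
                  title = "Simulated multichannel MUAP recording") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-unit accuracy of a match report
#'
#' @param object A `match_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot match_report
#' @export
autoplot.match_report <- function(object, ...) {
  df <- tidy(object)
  df <- tidyr::pivot_longer(
    df[, c("unit", "P", "R", "A")],
    c("P", "R", "A"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$unit), .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ground-truth unit", y = NULL,
                  title = "Per-unit precision / recall / accuracy") +
    ggplot2::theme_minimal()
}

#' Plot component and composite scores of a quality report
#'
#' @param object A `quality_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quality_report
#' @export
autoplot.quality_report <- function(object, ...) {
  df <- tidy(object)
  df <- tidyr::pivot_longer(
    df[, c("cluster", "S_T1", "S_T2", "S_FR", "S_SNR", "composite")],
    -"cluster", names_to = "score", values_to = "value"
  )
  df$score <- factor(df$score, c("S_T1", "S_T2", "S_FR", "S_SNR", "composite"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$score,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "cluster", y = NULL, fill = "score",
                  title = sprintf("Composite sort quality (overall %.3f)",
                                  overall_score(object))) +
    ggplot2::theme_minimal()
}

#' Plot the best-shift matrix of a delay plan
#'
#' @param object A `delay_plan` with its correlation structures.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delay_plan
#' @export
autoplot.delay_plan <- function(object, ...) {
  if (is.null(object$best_shift_matrix)) {
    stop("delay plan carries no best-shift matrix (loaded from JSON?)")
  }
  m <- object$best_shift_matrix
  df <- tibble::tibble(
    from = rep(seq_len(nrow(m)), ncol(m)),
    to = rep(seq_len(ncol(m)), each = nrow(m)),
    shift = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$shift)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "channel", y = "reference row",
                  fill = "best shift\n(samples)",
                  title = sprintf("Cross-channel delays (reference %d)",
                                  object$reference)) +
    ggplot2::theme_minimal()
}

#' Plot reconstructed unit templates of a basis
#'
#' @param basis A `muap_basis`.
#' @param units Units to draw (default all).
#' @return A ggplot, one facet per unit, offset channel traces.
#' @export
plot_templates <- function(basis, units = seq_len(basis$n_units)) {
  dfs <- lapply(units, function(u) {
    M <- reconstruct_template(basis, u)
    spread <- max(abs(M)) * 1.5
    tibble::tibble(
      unit = u,
      t = rep(seq_len(basis$nt) / basis$sampling_rate * 1000, ncol(M)),
      channel = rep(seq_len(ncol(M)), each = nrow(M)),
      v = as.vector(M) + rep(seq_len(ncol(M)), each = nrow(M)) * spread
    )
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(.data$t, .data$v, group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~unit, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "channel (offset)",
                  title = "Reconstructed multichannel templates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
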