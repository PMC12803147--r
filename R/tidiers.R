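#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return One row per truth unit (already tidy; strips the subclass).
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.match_report
#' @return `glance()`: one row with unit count and mean precision,
#'   recall, and accuracy (overall and overlap-restricted when present).
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  out <- tibble::tibble(
    n_units = nrow(x),
    n_matched = sum(!is.na(x$matched_cluster)),
    mean_precision = mean(x$P),
    mean_recall = mean(x$R),
    mean_accuracy = mean(x$A)
  )
  if ("A_overlap" %in% names(x)) {
    out$mean_accuracy_overlap <- mean(x$A_overlap)
  }
  out
}

#' Tidy a quality report
#'
#' @param x A `quality_report`.
#' @param ... Unused.
#' @method tidy quality_report
#' @export
tidy.quality_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.quality_report
#' @return `glance()`: one row with cluster count, overall (mean
#'   composite) score, and component means.
#' @method glance quality_report
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    overall = overall_score(x),
    mean_S_T1 = mean(x$S_T1), mean_S_T2 = mean(x$S_T2),
    mean_S_FR = mean(x$S_FR), mean_S_SNR = mean(x$S_SNR)
  )
}

#' Tidy a noise fit
#'
#' @param x A `noise_fit`.
#' @param ... Unused.
#' @return One row per channel: target, learned sigma, relative error.
#' @method tidy noise_fit
#' @export
tidy.noise_fit <- function(x, ...) {
  tibble::tibble(
    channel = seq_along(x$targets),
    target = x$targets,
    learned_sigma = x$learned
  )
}

#' @rdname tidy.noise_fit
#' @method glance noise_fit
#' @export
glance.noise_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    final_loss = x$loss[length(x$loss)]
  )
}
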