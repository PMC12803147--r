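# Run configuration, parameter-sweep expansion with linked parameters,
# run records, and ranking of sweep outputs by composite score.

#' Default run configuration
#'
#' A nested list mirroring the primary configuration file: `data`
#' (dataset type and passband), `sorting` (output folder, sweep flag,
#' swept parameter lists, linked groups), `group` (channel selection and
#' bad-channel method), and `algorithm` (detection thresholds, window
#' and template geometry, batch and whitening parameters, seed). Only
#' the `binary` dataset type is supported; other known types are
#' recognized but rejected at load time.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    data = list(
      dataset_type = "binary",
      emg_passband = c(250, 5000),
      time_range = NULL,
      recordings = list()
    ),
    sorting = list(
      output_folder = "sorted",
      do_sweep = FALSE,
      swept_params = list(),
      linked_params_for_sweep = list(c("Th_universal", "Th_learned"))
    ),
    group = list(
      emg_chan_list = NULL,
      remove_bad_emg_chans = "mad5"
    ),
    algorithm = list(
      Th_single_ch = c(6, 9, 12, 15),
      Th_universal = 9,
      Th_learned = 8,
      nt = 61,
      nskip = 2,
      n_pcs = 9,
      n_templates = 9,
      batch_size = 60000,
      whitening_range = 32,
      min_template_size = 10,
      template_sizes = 5,
      nearest_chans = 10,
      remove_chan_delays = TRUE,
      remove_spike_outliers = TRUE,
      hdbscan_min_cluster_size = 20,
      seed = 1
    )
  )
}

known_dataset_types <- c("binary", "openephys", "nwb", "blackrock", "intan")

#' Read and write run configurations (YAML)
#'
#' Parse -> serialize -> parse is a fixed point. Loading validates the
#' dataset type (only `binary` is implemented) and that every threshold
#' is positive.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dt <- cfg$data$dataset_type %||% "binary"
  if (!dt %in% known_dataset_types) stop("unknown dataset type: ", dt)
  if (dt != "binary") {
    stop("dataset type '", dt, "' is recognized but not supported; ",
         "convert the recording to flat binary")
  }
  for (nm in c("Th_single_ch", "Th_universal", "Th_learned")) {
    v <- cfg$algorithm[[nm]]
    if (!is.null(v) && any(unlist(v) <= 0)) {
      stop("thresholds must be positive: ", nm)
    }
  }
  cfg
}

#' @rdname read_config
#' @param config Nested configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Expand a parameter sweep
#'
#' Takes a map from parameter name to a list of candidate values and a
#' list of linked groups. Unlinked parameters combine by Cartesian
#' product; parameters in a linked group advance their indexes together
#' (only matching indexes form valid combinations), so lists within a
#' group must have equal lengths. Order is deterministic: the last
#' factor varies fastest.
#'
#' @param swept Named list: parameter name -> list/vector of values.
#' @param linked List of character vectors naming linked groups.
#' @return List of named parameter combinations.
#' @export
expand_sweep <- function(swept, linked = list()) {
  if (!length(swept)) return(list(stats::setNames(list(), character(0))))
  nm <- names(swept)
  lens <- vapply(swept, length, integer(1))
  for (g in linked) {
    g <- intersect(g, nm)
    if (length(g) > 1L && length(unique(lens[g])) != 1L) {
      stop("linked parameter lists must be equal length: ",
           paste(g, collapse = ", "))
    }
  }
  # factors: each linked group (of swept names) is one factor; the rest
  # are singleton factors
  in_group <- unlist(lapply(linked, intersect, nm))
  factors <- c(
    lapply(Filter(function(g) length(g) > 0L, lapply(linked, intersect, nm)),
           identity),
    as.list(setdiff(nm, in_group))
  )
  factor_len <- vapply(factors, function(g) lens[[g[1]]], integer(1))
  idx_grid <- expand.grid(rev(lapply(factor_len, seq_len)),
                          KEEP.OUT.ATTRS = FALSE)
  idx_grid <- idx_grid[, rev(seq_along(factors)), drop = FALSE]
  lapply(seq_len(nrow(idx_grid)), function(r) {
    combo <- list()
    for (f in seq_along(factors)) {
      i <- idx_grid[r, f]
      for (p in factors[[f]]) combo[[p]] <- swept[[p]][[i]]
    }
    combo[nm]
  })
}

#' Record a completed run
#'
#' Writes the configuration snapshot (with appended result fields) into
#' the run's output folder and renames the folder so its name carries
#' the overall composite score to 4 decimals (`<folder>.score_<value>`).
#'
#' @param config Configuration list used for the run.
#' @param results Named list of result fields (e.g. `num_chans`,
#'   `emg_chan_noise`, `cluster_scores`); must include `overall_score`.
#' @param folder Existing run output folder.
#' @return The new folder path (invisibly).
#' @export
run_record <- function(config, results, folder) {
  if (!dir.exists(folder)) stop("unwritable or missing run folder: ", folder)
  config$Results <- results
  write_config(config, file.path(folder, "config_snapshot.yaml"))
  overall <- results$overall_score
  if (!is.null(overall)) {
    new <- paste0(sub("/+$", "", folder), sprintf(".score_%.4f", overall))
    file.rename(folder, new)
    return(invisible(new))
  }
  invisible(folder)
}

#' Rank sweep runs by composite score
#'
#' Scans a parent folder for run folders whose names carry a
#' `.score_<value>` suffix and orders them by score, descending; ties
#' keep folder-timestamp order, and folders without a score rank last
#' with a warning.
#'
#' @param parent Folder containing run folders.
#' @return Tibble `folder`, `score`, ordered best first.
#' @export
rank_runs <- function(parent) {
  dirs <- list.dirs(parent, recursive = FALSE)
  if (!length(dirs)) stop("no run folders under ", parent)
  scores <- suppressWarnings(
    as.numeric(sub(".*\\.score_([0-9.]+)$", "\\1",
                   ifelse(grepl("\\.score_[0-9.]+$", dirs), dirs, NA)))
  )
  if (any(is.na(scores))) {
    warning(sum(is.na(scores)), " run folder(s) without a score; ranked last")
  }
  mtimes <- file.info(dirs)$mtime
  ord <- order(-ifelse(is.na(scores), -Inf, scores), mtimes)
  tibble::tibble(folder = dirs[ord], score = scores[ord])
}
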