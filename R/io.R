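#' Read a multichannel recording from CSV or EDF
#'
#' CSV dialect: a header row of channel labels, one sample per row,
#' numeric cells only (the sampling rate is not stored in CSV and must be
#' supplied). EDF files carry their own sampling rate and labels; channels
#' are returned in file order unless `channels` requests a specific order.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @param fs Sampling rate in Hz (required for CSV, ignored for EDF).
#' @param channels Optional label vector: select/reorder channels to this
#'   order (error if any is missing).
#' @param subject_id,group Metadata attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = NULL, fs = NULL, channels = NULL,
                           subject_id = basename(path), group = "unknown") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    if (is.null(fs)) stop("fs must be supplied for CSV input", call. = FALSE)
    header <- strsplit(readLines(path, n = 1L), ",")[[1]]
    header <- trimws(header)
    if (length(header) == 0L || any(!nzchar(header)) ||
        !any(is.na(suppressWarnings(as.numeric(header))))) {
      stop("CSV is missing a channel-label header row", call. = FALSE)
    }
    if (anyDuplicated(header)) {
      stop("duplicated channel labels in CSV header", call. = FALSE)
    }
    df <- utils::read.csv(path, check.names = FALSE)
    for (cn in seq_along(df)) {
      col <- df[[cn]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))
        stop(sprintf("non-numeric cell in column '%s', row %d",
                     names(df)[cn], bad[1]), call. = FALSE)
      }
    }
    dat <- t(as.matrix(df))
    rec <- eeg_recording(dat, fs, names(df), subject_id, group)
  } else {
    rec <- read_edf(path, subject_id = subject_id, group = group)
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec$channel_labels)
    if (length(missing)) {
      stop(sprintf("requested channels not in file: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    rec <- eeg_recording(rec$data[channels, , drop = FALSE], rec$fs,
                         channels, rec$subject_id, rec$group)
  }
  rec
}

#' Write a recording to CSV or EDF
#'
#' CSV: header row of channel labels, one sample per row (lossless). EDF:
#' standard 16-bit encoding, which quantizes amplitudes to the per-channel
#' physical range over 65536 digital levels.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"csv"` or `"edf"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    # %.17g round-trips doubles exactly, so CSV export is lossless
    df <- as.data.frame(lapply(seq_len(nrow(rec$data)), function(ch)
      sprintf("%.17g", rec$data[ch, ])))
    names(df) <- rec$channel_labels
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Write a cohort to per-subject CSVs plus a manifest
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest tibble (with a `file` column).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$file <- file.path(dir, paste0(manifest$subject_id, ".csv"))
  for (r in seq_len(nrow(manifest))) {
    write_recording(cohort$recordings[[manifest$subject_id[r]]],
                    manifest$file[r])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Serialize / restore a truth or pipeline configuration as YAML
#'
#' @param x A [synthetic_truth()] or [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   restored object.
#' @export
write_config <- function(x, path) {
  if (inherits(x, "synthetic_truth")) {
    y <- list(type = "synthetic_truth",
              bands = lapply(x$bands, function(b)
                list(name = b$name, f_lo = b$f_lo, f_hi = b$f_hi)),
              groups = as.list(x$groups),
              coupling = lapply(x$coupling, function(g)
                lapply(g, function(K) apply(K, 1, as.numeric,
                                            simplify = FALSE))),
              f0 = as.list(x$f0), f_jitter_sd = as.list(x$f_jitter_sd),
              sigma = x$sigma, amplitudes = as.list(x$amplitudes),
              noise_amp = x$noise_amp, noise_exponent = x$noise_exponent,
              linkages = lapply(x$linkages, unclass),
              fs = x$fs, dur_s = x$dur_s, n_channels = x$n_channels,
              channel_labels = x$channel_labels, seed = x$seed)
  } else if (inherits(x, "pipeline_config")) {
    y <- list(type = "pipeline_config",
              bands = lapply(x$bands, function(b)
                list(name = b$name, f_lo = b$f_lo, f_hi = b$f_hi)),
              schemes = lapply(x$schemes, function(s)
                list(length_s = s$length_s, overlap_frac = s$overlap_frac)),
              trim_s = x$trim_s, filter_order = x$filter_order,
              partition = as.list(x$partition),
              weight_mode = x$weight_mode, length_map = x$length_map,
              crossband_mode = x$crossband_mode,
              state_features = x$state_features,
              dynamics_orders = x$dynamics_orders,
              kmeans_replicates = x$kmeans_replicates,
              q_star = x$q_star, variant = x$variant, seed = x$seed,
              run_dynamics = x$run_dynamics,
              run_crossband = x$run_crossband)
  } else {
    stop("write_config handles synthetic_truth and pipeline_config objects",
         call. = FALSE)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- stats::setNames(
    lapply(y$bands, function(b) band_spec(b$name, b$f_lo, b$f_hi)),
    vapply(y$bands, `[[`, character(1), "name"))
  if (identical(y$type, "synthetic_truth")) {
    coupling <- lapply(y$coupling, function(g)
      lapply(g, function(rows) do.call(rbind, lapply(rows, as.numeric))))
    linkages <- lapply(y$linkages, function(lk)
      cross_band_linkage(lk$band_from, lk$band_to, lk$ch_from, lk$ch_to,
                         lk$strength, lk$n, lk$m, lk$group))
    synthetic_truth(
      bands = bands, groups = unlist(y$groups), coupling = coupling,
      f0 = unlist(y$f0), f_jitter_sd = unlist(y$f_jitter_sd),
      sigma = y$sigma, amplitudes = unlist(y$amplitudes),
      noise_amp = y$noise_amp, noise_exponent = y$noise_exponent,
      linkages = linkages, fs = y$fs, dur_s = y$dur_s,
      n_channels = y$n_channels, channel_labels = y$channel_labels,
      seed = y$seed)
  } else if (identical(y$type, "pipeline_config")) {
    schemes <- stats::setNames(
      lapply(y$schemes, function(s) window_scheme(s$length_s,
                                                  s$overlap_frac)),
      names(y$schemes))
    pipeline_config(
      bands = bands, schemes = schemes, trim_s = y$trim_s,
      filter_order = y$filter_order, partition = unlist(y$partition),
      weight_mode = y$weight_mode, length_map = y$length_map,
      crossband_mode = y$crossband_mode, state_features = y$state_features,
      dynamics_orders = unlist(y$dynamics_orders),
      kmeans_replicates = y$kmeans_replicates, q_star = y$q_star,
      variant = y$variant, seed = y$seed, run_dynamics = y$run_dynamics,
      run_crossband = y$run_crossband)
  } else {
    stop("unknown or missing config type in YAML", call. = FALSE)
  }
}
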