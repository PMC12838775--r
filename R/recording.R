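#' Multichannel EEG recording
#'
#' Light container for a channels x samples amplitude matrix with its
#' sampling rate and channel labels. The default montage is the eight
#' 10-20 sites F3, F4, T3, C3, C4, T4, O1, O2.
#'
#' @param data Numeric matrix, channels x samples, all finite.
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_labels Character vector of unique labels, one per row of
#'   `data`. Defaults to rownames of `data` or [default_channels()].
#' @param subject_id Subject identifier string.
#' @param group Group label string (e.g. `"TD"`, `"ASD"`).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "S1", group = "unknown") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) {
      channel_labels <- if (nrow(data) == 8L) default_channels() else
        paste0("ch", seq_len(nrow(data)))
    }
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels must match the number of rows of data",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "eeg_recording"
  )
}

#' Default 10-20 channel montage
#'
#' @return The eight sensor labels F3, F4, T3, C3, C4, T4, O1, O2.
#' @export
default_channels <- function() {
  c("F3", "F4", "T3", "C3", "C4", "T4", "O1", "O2")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)>\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' @describeIn eeg_recording Long-format view: one row per (channel, sample).
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    channel = rep(x$channel_labels, each = n),
    time_s = rep(seq_len(n) - 1L, times = nrow(x$data)) / x$fs,
    value = as.vector(t(x$data))
  )
}
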