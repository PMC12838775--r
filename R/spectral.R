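#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass applied
#' forward-backward ([signal::filtfilt()]), so the output has no phase
#' distortion — essential here because instantaneous phase is the quantity
#' of interest downstream.
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_spec()]; `f_hi` must be below the Nyquist frequency.
#' @param order Butterworth order of the one-pass prototype (default 4; the
#'   forward-backward application doubles the effective roll-off).
#' @return A filtered [eeg_recording()], channel order preserved.
#' @export
bandpass <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  nyq <- rec$fs / 2
  if (band$f_hi >= nyq) {
    stop(sprintf("invalid band: f_hi = %g Hz >= Nyquist (%g Hz)",
                 band$f_hi, nyq), call. = FALSE)
  }
  n <- ncol(rec$data)
  if (n < 3L * (2L * order + 1L)) {
    stop("signal shorter than filter warm-up", call. = FALSE)
  }
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  }
  eeg_recording(out, rec$fs, rec$channel_labels, rec$subject_id, rec$group)
}

#' Optional broadband preprocessing
#'
#' Convenience plumbing for real recordings: a power-line notch and/or a
#' broadband band-pass, both zero-phase. Synthetic cohorts do not need
#' either; both steps are off unless requested.
#'
#' @param rec An [eeg_recording()].
#' @param notch_hz Power-line frequency to notch out (e.g. 50), or `NULL`.
#' @param broadband Length-2 numeric band (Hz) for a broadband pass (e.g.
#'   `c(0.5, 45)`), or `NULL`.
#' @param rereference If `TRUE`, subtract the common average across channels
#'   at every sample.
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess <- function(rec, notch_hz = NULL, broadband = NULL,
                       rereference = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  if (!is.null(notch_hz)) {
    nyq <- out$fs / 2
    w <- c(notch_hz - 1, notch_hz + 1) / nyq
    bf <- signal::butter(2, w, type = "stop")
    dat <- out$data
    for (ch in seq_len(nrow(dat))) dat[ch, ] <- signal::filtfilt(bf, dat[ch, ])
    out <- eeg_recording(dat, out$fs, out$channel_labels, out$subject_id,
                         out$group)
  }
  if (!is.null(broadband)) {
    out <- bandpass(out, band_spec("broadband", broadband[1], broadband[2]))
  }
  if (rereference) {
    dat <- sweep(out$data, 2, colMeans(out$data))
    out <- eeg_recording(dat, out$fs, out$channel_labels, out$subject_id,
                         out$group)
  }
  out
}

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a single-channel signal
#'
#' Phase of the analytic signal (Hilbert transform), i.e. the four-quadrant
#' angle `Arg(x + i H[x])`, wrapped to `(-pi, pi]`.
#'
#' @param x Numeric vector, finite, length >= 2, non-constant.
#' @param fs Sampling rate in Hz (carried for provenance; the phase itself
#'   is dimensionless).
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(x, fs = NULL) {
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x))) {
    stop("signal must be finite and of length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("undefined phase: constant (zero-variance) signal", call. = FALSE)
  }
  Arg(analytic_signal(x))
}

#' Per-band instantaneous phase tensor
#'
#' Band-passes a recording and extracts per-channel instantaneous phases;
#' the first and last `trim_s` seconds are marked invalid (filter/Hilbert
#' edge artifacts) and excluded from all downstream PLV computations via the
#' `valid` range.
#'
#' @param rec An [eeg_recording()] (already band-limited or raw).
#' @param band The [band_spec()] this tensor represents.
#' @param trim_s Seconds to trim from each end.
#' @param filter If `TRUE` (default) apply [bandpass()] first; set `FALSE`
#'   when `rec` is already band-limited.
#' @param order Butterworth order passed to [bandpass()].
#' @return A `band_phase_tensor`: list with `band`, `fs`, `phases`
#'   (channels x samples, radians), `valid` (first/last retained sample
#'   index) and `channel_labels`.
#' @export
band_phase_tensor <- function(rec, band, trim_s = 1, filter = TRUE,
                              order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  n <- ncol(rec$data)
  trim_n <- as.integer(round(trim_s * rec$fs))
  if (2L * trim_n >= n) {
    stop("recording too short after trimming", call. = FALSE)
  }
  src <- if (filter) bandpass(rec, band, order = order) else rec
  ph <- matrix(0, nrow(src$data), n)
  for (ch in seq_len(nrow(src$data))) {
    ph[ch, ] <- instantaneous_phase(src$data[ch, ])
  }
  rownames(ph) <- rec$channel_labels
  structure(list(band = band, fs = rec$fs, phases = ph,
                 valid = c(trim_n + 1L, n - trim_n),
                 channel_labels = rec$channel_labels),
            class = "band_phase_tensor")
}

#' @export
print.band_phase_tensor <- function(x, ...) {
  cat(sprintf("<band_phase_tensor %s: %d ch x %d samples, valid [%d, %d]>\n",
              format(x$band), nrow(x$phases), ncol(x$phases),
              x$valid[1], x$valid[2]))
  invisible(x)
}

# valid-range phase matrix (channels x valid samples)
valid_phases <- function(tensor) {
  tensor$phases[, tensor$valid[1]:tensor$valid[2], drop = FALSE]
}

#' Decompose a recording into per-band phase tensors
#'
#' @param rec An [eeg_recording()].
#' @param bands Named list of [band_spec()]s (default the four canonical
#'   bands).
#' @param trim_s Seconds trimmed from each end of every tensor.
#' @param order Butterworth order.
#' @return Named list of `band_phase_tensor`s, one per band.
#' @export
band_phases <- function(rec, bands = default_bands(), trim_s = 1,
                        order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  lapply(bands, function(b) band_phase_tensor(rec, b, trim_s = trim_s,
                                              order = order))
}
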