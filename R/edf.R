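# Minimal European Data Format (EDF) support: plain continuous EDF with
# 16-bit samples, equal sampling rate across channels. Covers the standard
# header + per-signal header + little-endian int16 data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Amplitudes are quantized to each channel's physical range over the
#' 16-bit digital range; round-tripping is therefore exact only up to that
#' quantization step.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  # one-second records when the sample count allows, one big record otherwise
  if (rec$fs == round(rec$fs) && n %% rec$fs == 0) {
    n_rec <- n %/% rec$fs
    rec_dur <- 1
    spr <- as.integer(rec$fs)
  } else {
    n_rec <- 1L
    rec_dur <- n / rec$fs
    spr <- n
  }
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wtxt <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                       eos = NULL)
  header_bytes <- 256L + 256L * ns
  wtxt("0", 8)
  wtxt(rec$subject_id, 80)
  wtxt(paste("group", rec$group), 80)
  wtxt("01.01.00", 8)
  wtxt("00.00.00", 8)
  wtxt(header_bytes, 8)
  wtxt("", 44)
  wtxt(n_rec, 8)
  wtxt(format(rec_dur, digits = 7), 8)
  wtxt(ns, 4)
  for (lab in rec$channel_labels) wtxt(lab, 16)
  for (i in seq_len(ns)) wtxt("", 80)                      # transducer
  for (i in seq_len(ns)) wtxt("uV", 8)                     # physical dim
  for (i in seq_len(ns)) wtxt(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) wtxt(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) wtxt(dmin, 8)
  for (i in seq_len(ns)) wtxt(dmax, 8)
  for (i in seq_len(ns)) wtxt("", 80)                      # prefiltering
  for (i in seq_len(ns)) wtxt(spr, 8)
  for (i in seq_len(ns)) wtxt("", 32)
  scale <- (dmax - dmin) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((rec$data[ch, idx] - phys_min[ch]) * scale[ch] +
                                dmin))
      dig <- as.integer(base::pmin(base::pmax(dig, dmin), dmax))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a plain continuous EDF file
#'
#' @param path EDF file path.
#' @param subject_id,group Metadata for the returned recording (default
#'   subject id from the file's patient field).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, group = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rtxt <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rtxt(8)
  patient <- rtxt(80)
  rtxt(80); rtxt(8); rtxt(8)
  rtxt(8)                                  # header bytes (recomputed)
  rtxt(44)
  n_rec <- as.integer(rtxt(8))
  rec_dur <- as.numeric(rtxt(8))
  ns <- as.integer(rtxt(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L) {
    stop("not a parseable EDF header", call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rtxt(16), character(1))
  for (i in seq_len(ns)) rtxt(80)
  for (i in seq_len(ns)) rtxt(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rtxt(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rtxt(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rtxt(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rtxt(8)), numeric(1))
  for (i in seq_len(ns)) rtxt(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rtxt(8)), integer(1))
  for (i in seq_len(ns)) rtxt(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicated channel labels in EDF", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  dat <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      dat[ch, idx] <- (dig - dmin[ch]) * (phys_max[ch] - phys_min[ch]) /
        (dmax[ch] - dmin[ch]) + phys_min[ch]
    }
  }
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(patient)) patient else basename(path)
  }
  eeg_recording(dat, fs, labels, subject_id, group)
}
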