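#' Frequency band specification
#'
#' A band is a named frequency interval `[f_lo, f_hi)` in Hz. The four
#' canonical EEG rhythms used throughout the package are delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz); see
#' [default_bands()].
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return A `band_spec` object.
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || !is.finite(f_lo) || !is.finite(f_hi) ||
      f_lo <= 0 || f_hi <= f_lo) {
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' @export
format.band_spec <- function(x, ...) {
  sprintf("%s (%g-%g Hz)", x$name, x$f_lo, x$f_hi)
}

#' Canonical EEG frequency bands
#'
#' @return Named list of [band_spec()] objects: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30 Hz.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 13),
    beta  = band_spec("beta", 13, 30)
  )
}

#' Band center frequency
#'
#' Arithmetic midpoint of the band edges, used as the default oscillator
#' frequency in the synthetic generator and for n:m ratio rounding.
#'
#' @param band A [band_spec()].
#' @return Center frequency in Hz.
#' @export
band_center <- function(band) {
  stopifnot(inherits(band, "band_spec"))
  (band$f_lo + band$f_hi) / 2
}

#' The six unordered pairs of the four canonical bands
#'
#' @param bands Named list of bands (default [default_bands()]).
#' @return A tibble with columns `band_a`, `band_b` (names), one row per
#'   unordered pair, in delta-theta, delta-alpha, delta-beta, theta-alpha,
#'   theta-beta, alpha-beta order.
#' @export
band_pairs <- function(bands = default_bands()) {
  nm <- names(bands)
  stopifnot(length(nm) >= 2L)
  idx <- utils::combn(seq_along(nm), 2L)
  tibble::tibble(band_a = nm[idx[1L, ]], band_b = nm[idx[2L, ]])
}
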