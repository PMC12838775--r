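#' Helper: symmetric coupling matrix from an edge list
#'
#' Builds the channels x channels Kuramoto coupling matrix K used by the
#' synthetic generator: symmetric, zero diagonal, nonnegative (rad/s).
#'
#' @param n_channels Number of channels.
#' @param edges Two-column matrix (or list of length-2 vectors) of channel
#'   index pairs, or `NULL` for no coupling.
#' @param strength Coupling strength(s) in rad/s, recycled over edges.
#' @return An `n_channels` x `n_channels` numeric matrix.
#' @examples
#' coupling_matrix(4, rbind(c(1, 2), c(3, 4)), strength = 2)
#' @export
coupling_matrix <- function(n_channels, edges = NULL, strength = 0) {
  K <- matrix(0, n_channels, n_channels)
  if (is.null(edges)) return(K)
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2L)
  strength <- rep_len(strength, nrow(edges))
  if (any(strength < 0)) stop("coupling strengths must be nonnegative",
                              call. = FALSE)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    if (i == j) stop("coupling edges must join distinct channels",
                     call. = FALSE)
    K[i, j] <- K[i, j] + strength[e]
    K[j, i] <- K[i, j]
  }
  K
}

#' Cross-band phase linkage specification
#'
#' Declares that in band `band_to`, channel `ch_to`'s phase is slaved to
#' channel `ch_from`'s phase in `band_from` as an n:m harmonic:
#' `phi_to = (n/m) * phi_from + (1 - strength) * jitter`, where the jitter is
#' an independent phase random walk. `strength = 1` gives perfect n:m
#' locking, `strength = 0` a fully independent phase.
#'
#' @param band_from,band_to Band names (must differ).
#' @param ch_from,ch_to Channel indices.
#' @param strength Linkage strength in `[0, 1]`.
#' @param n,m Positive integers of the n:m ratio (target advances n cycles
#'   per m source cycles).
#' @param group Optional group label; `NULL` applies the linkage to all
#'   groups.
#' @return A `cross_band_linkage` list.
#' @export
cross_band_linkage <- function(band_from, band_to, ch_from, ch_to,
                               strength = 1, n = 1L, m = 1L, group = NULL) {
  stopifnot(band_from != band_to, strength >= 0, strength <= 1,
            n >= 1, m >= 1, n == round(n), m == round(m))
  structure(list(band_from = band_from, band_to = band_to,
                 ch_from = as.integer(ch_from), ch_to = as.integer(ch_to),
                 strength = strength, n = as.integer(n), m = as.integer(m),
                 group = group),
            class = "cross_band_linkage")
}

#' Ground-truth specification for a synthetic EEG cohort
#'
#' Defines the generative model of the synthetic-data module: per band a
#' population of noisy Kuramoto phase oscillators (one per channel) whose
#' pairwise coupling matrix K is group-specific, summed over bands as
#' `amplitude * cos(phase)` plus 1/f^beta background noise. All quantities
#' are a planted, recoverable ground truth for the downstream pipeline.
#'
#' Defaults mirror an eyes-open resting-state pediatric protocol: 8 channels
#' of the 10-20 montage, 1000 Hz sampling, 300 s per subject, two groups of
#' 36 subjects.
#'
#' @param bands Named list of [band_spec()]s.
#' @param groups Named integer vector of group sizes (each >= 2).
#' @param coupling Nested named list `coupling[[group]][[band]]` of coupling
#'   matrices (see [coupling_matrix()]); missing entries default to zero
#'   coupling.
#' @param f0 Named numeric vector of oscillator center frequencies (Hz), one
#'   per band; defaults to the band midpoints. Must lie inside the band.
#' @param f_jitter_sd Per-band sd of the subject-level center-frequency
#'   jitter (Hz).
#' @param sigma Phase-noise intensity in rad/sqrt(s).
#' @param amplitudes Named per-band oscillation amplitudes (signal units).
#' @param noise_amp Amplitude of the 1/f background noise component.
#' @param noise_exponent Spectral exponent beta of the 1/f^beta background.
#' @param linkages List of [cross_band_linkage()]s.
#' @param fs Sampling rate in Hz.
#' @param dur_s Recording duration in seconds.
#' @param n_channels Number of channels.
#' @param channel_labels Channel labels.
#' @param seed Base random seed; fixes the whole cohort bit-for-bit.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(bands = default_bands(),
                            groups = c(TD = 36L, ASD = 36L),
                            coupling = list(),
                            f0 = NULL,
                            f_jitter_sd = 0.1,
                            sigma = 1.5,
                            amplitudes = NULL,
                            noise_amp = 0.5,
                            noise_exponent = 1,
                            linkages = list(),
                            fs = 1000,
                            dur_s = 300,
                            n_channels = 8L,
                            channel_labels = NULL,
                            seed = 1L) {
  stopifnot(length(bands) >= 1L, !is.null(names(bands)))
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels == 8L) default_channels() else
      paste0("ch", seq_len(n_channels))
  }
  stopifnot(length(channel_labels) == n_channels)
  if (fs <= 0 || dur_s <= 0) {
    stop("fs and dur_s must be positive", call. = FALSE)
  }
  if (any(groups < 2L)) stop("each group needs >= 2 subjects", call. = FALSE)
  if (is.null(names(groups))) stop("groups must be named", call. = FALSE)
  if (is.null(f0)) f0 <- vapply(bands, band_center, numeric(1))
  f0 <- f0[names(bands)]
  for (b in names(bands)) {
    if (!is.finite(f0[[b]]) || f0[[b]] <= bands[[b]]$f_lo ||
        f0[[b]] >= bands[[b]]$f_hi) {
      stop(sprintf("f0 for band '%s' must lie inside (%g, %g) Hz", b,
                   bands[[b]]$f_lo, bands[[b]]$f_hi), call. = FALSE)
    }
  }
  if (is.null(amplitudes)) {
    amplitudes <- stats::setNames(rep(1, length(bands)), names(bands))
  }
  f_jitter_sd <- rep_len(f_jitter_sd, length(bands))
  names(f_jitter_sd) <- names(bands)
  # fill in missing / validate coupling matrices
  full <- list()
  for (g in names(groups)) {
    full[[g]] <- list()
    for (b in names(bands)) {
      K <- coupling[[g]][[b]]
      if (is.null(K)) K <- matrix(0, n_channels, n_channels)
      if (!is.matrix(K) || any(dim(K) != n_channels)) {
        stop(sprintf("coupling[['%s']][['%s']] must be %d x %d",
                     g, b, n_channels, n_channels), call. = FALSE)
      }
      if (any(K < 0) || any(abs(K - t(K)) > 1e-12) || any(diag(K) != 0)) {
        stop("coupling matrices must be symmetric, nonnegative, zero-diagonal",
             call. = FALSE)
      }
      full[[g]][[b]] <- K
    }
  }
  for (lk in linkages) {
    stopifnot(inherits(lk, "cross_band_linkage"))
    if (!lk$band_from %in% names(bands) || !lk$band_to %in% names(bands)) {
      stop("linkage refers to an unknown band", call. = FALSE)
    }
    if (!is.null(lk$group) && !lk$group %in% names(groups)) {
      stop("linkage refers to an unknown group", call. = FALSE)
    }
  }
  structure(
    list(bands = bands, groups = groups, coupling = full, f0 = f0,
         f_jitter_sd = f_jitter_sd, sigma = sigma, amplitudes = amplitudes,
         noise_amp = noise_amp, noise_exponent = noise_exponent,
         linkages = linkages, fs = fs, dur_s = dur_s,
         n_channels = as.integer(n_channels),
         channel_labels = channel_labels, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth: %d ch, %g Hz, %g s; groups %s; bands %s; %d linkage(s)>\n",
    x$n_channels, x$fs, x$dur_s,
    paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
    paste(names(x$bands), collapse = "/"), length(x$linkages)))
  invisible(x)
}

# 1/f^beta Gaussian background noise via spectral shaping, unit sd per row.
onef_noise <- function(n_channels, n, fs, beta) {
  out <- matrix(0, n_channels, n)
  freqs <- seq_len(n %/% 2)  # positive frequency bins
  scale <- freqs^(-beta / 2)
  for (ch in seq_len(n_channels)) {
    w <- stats::fft(rnorm(n))
    shape <- numeric(n)
    shape[1L] <- 0
    shape[1L + freqs] <- scale
    if (n > 2L) shape[n + 1L - seq_len((n - 1L) %/% 2)] <-
        scale[seq_len((n - 1L) %/% 2)]
    x <- Re(stats::fft(w * shape, inverse = TRUE)) / n
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

# deterministic per-subject seed from base seed, group index and subject index
derive_seed <- function(base_seed, group_idx, subj_idx) {
  as.integer((as.double(base_seed) + 999983 * group_idx + 7919 * subj_idx) %%
               2147483647)
}

#' Simulate one synthetic EEG subject
#'
#' Integrates, per band, the stochastic Kuramoto dynamics
#' `dphi_i = 2 pi f_b dt + sum_j K_ij sin(phi_j - phi_i) dt + sigma dW_i`
#' with Euler-Maruyama steps at the recording sampling rate, applies any
#' cross-band linkages, and sums `amplitude_b * cos(phi_b)` over bands plus
#' `noise_amp` x 1/f^beta background noise.
#'
#' @param truth A [synthetic_truth()].
#' @param group Group label (must be one of `names(truth$groups)`).
#' @param subject_seed Integer seed; same truth + same seed gives a
#'   bit-identical recording.
#' @param subject_id Subject identifier.
#' @return An [eeg_recording()].
#' @export
simulate_subject <- function(truth, group, subject_seed,
                             subject_id = paste0(group, "_", subject_seed)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!group %in% names(truth$groups)) {
    stop(sprintf("unknown group label '%s'", group), call. = FALSE)
  }
  n <- as.integer(round(truth$dur_s * truth$fs))
  if (n <= 1L) stop("invalid configuration: empty recording", call. = FALSE)
  dt <- 1 / truth$fs
  set.seed(as.integer(subject_seed))
  phases <- list()
  for (b in names(truth$bands)) {
    phi0 <- runif(truth$n_channels, -pi, pi)
    omega <- 2 * pi * (truth$f0[[b]] +
                         rnorm(truth$n_channels, 0, truth$f_jitter_sd[[b]]))
    phi <- kuramoto_integrate(phi0, omega, truth$coupling[[group]][[b]],
                              truth$sigma, dt, n - 1L)
    phases[[b]] <- phi
  }
  for (lk in truth$linkages) {
    if (!is.null(lk$group) && lk$group != group) next
    jitter <- phase_random_walk(runif(1, -pi, pi), truth$sigma, dt, n - 1L)
    phases[[lk$band_to]][lk$ch_to, ] <-
      (lk$n / lk$m) * phases[[lk$band_from]][lk$ch_from, ] +
      (1 - lk$strength) * jitter
  }
  x <- matrix(0, truth$n_channels, n)
  for (b in names(truth$bands)) {
    x <- x + truth$amplitudes[[b]] * cos(phases[[b]])
  }
  if (truth$noise_amp > 0) {
    x <- x + truth$noise_amp *
      onef_noise(truth$n_channels, n, truth$fs, truth$noise_exponent)
  }
  eeg_recording(x, truth$fs, truth$channel_labels,
                subject_id = subject_id, group = group)
}

#' Simulate a full synthetic cohort
#'
#' One recording per subject; subject seeds are derived deterministically
#' from the truth's base seed, the group index and the subject index, so a
#' fixed truth reproduces the cohort bit-for-bit.
#'
#' @param truth A [synthetic_truth()].
#' @return An `eeg_cohort`: list with `recordings` (list of
#'   [eeg_recording()]), `manifest` (tibble: subject_id, group, seed) and the
#'   `truth` used.
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  recs <- list()
  rows <- list()
  for (gi in seq_along(truth$groups)) {
    g <- names(truth$groups)[gi]
    for (si in seq_len(truth$groups[[gi]])) {
      sid <- sprintf("%s_%02d", g, si)
      sseed <- derive_seed(truth$seed, gi, si)
      recs[[sid]] <- simulate_subject(truth, g, sseed, subject_id = sid)
      rows[[sid]] <- tibble::tibble(subject_id = sid, group = g, seed = sseed)
    }
  }
  structure(list(recordings = recs,
                 manifest = dplyr::bind_rows(rows),
                 truth = truth),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<eeg_cohort: %d subjects (%s)>\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
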