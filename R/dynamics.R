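#' Sliding-window scheme
#'
#' @param length_s Window length in seconds (> 0).
#' @param overlap_frac Overlap fraction in `[0, 1)`; the step is
#'   `length_s * (1 - overlap_frac)`. Default 0.2 (20% overlap).
#' @return A `window_scheme` object with derived `step_s`.
#' @export
window_scheme <- function(length_s, overlap_frac = 0.2) {
  stopifnot(length_s > 0, overlap_frac >= 0, overlap_frac < 1)
  structure(list(length_s = length_s, overlap_frac = overlap_frac,
                 step_s = length_s * (1 - overlap_frac)),
            class = "window_scheme")
}

#' The six canonical window lengths
#'
#' 0.5, 1, 2, 4, 6 and 8 s, all at 20% overlap — spanning sub-second rapid
#' regulation through multi-second slow dynamics.
#'
#' @return Named list of [window_scheme()]s.
#' @export
default_window_schemes <- function() {
  lens <- c(0.5, 1, 2, 4, 6, 8)
  stats::setNames(lapply(lens, window_scheme),
                  paste0("w", sub("\\.", "p", format(lens))))
}

#' Sliding-window sample ranges
#'
#' Half-open ranges over the valid samples: window w covers samples
#' `[(w-1)*step, (w-1)*step + length)`, step rounded to integer samples,
#' last partial window dropped. Count is
#' `floor((n_valid - length) / step) + 1`.
#'
#' @param n_valid_samples Number of valid samples available.
#' @param fs Sampling rate in Hz.
#' @param scheme A [window_scheme()].
#' @return Tibble with 1-based inclusive `start`, `end` sample indices and
#'   `start_s` (seconds from the first valid sample).
#' @export
window_slices <- function(n_valid_samples, fs, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  len <- as.integer(round(scheme$length_s * fs))
  step <- as.integer(round(scheme$step_s * fs))
  if (len < 2L || step < 1L) stop("degenerate window scheme", call. = FALSE)
  if (n_valid_samples < len) {
    stop("window longer than available signal", call. = FALSE)
  }
  n_win <- (n_valid_samples - len) %/% step + 1L
  start <- (seq_len(n_win) - 1L) * step + 1L
  tibble::tibble(start = start, end = start + len - 1L,
                 start_s = (start - 1L) / fs)
}

#' Dynamic (windowed) connectivity series
#'
#' Per-window low-order PLV matrices (or band-pair matrices when `tensor_b`
#' is given), with `order = "high"` applying [hofc()] to each window's
#' low-order matrix; the static degenerate-edge policy applies per window.
#'
#' @param tensor A [band_phase_tensor()].
#' @param scheme A [window_scheme()].
#' @param order `"low"` or `"high"`.
#' @param tensor_b Optional second-band tensor for between-frequency
#'   windows.
#' @param mode,ratio Passed to [cross_band_lofc()] when `tensor_b` is given.
#' @return A `network_series`: list with `scheme`, `band`, `order`,
#'   `matrices` (list of [connectivity_matrix()]) and `window_starts_s`.
#' @export
dynamic_networks <- function(tensor, scheme, order = c("low", "high"),
                             tensor_b = NULL, mode = "one_to_one",
                             ratio = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(tensor, "band_phase_tensor"))
  n_valid <- tensor$valid[2] - tensor$valid[1] + 1L
  slices <- window_slices(n_valid, tensor$fs, scheme)
  mats <- vector("list", nrow(slices))
  for (w in seq_len(nrow(slices))) {
    sub <- window_tensor(tensor, slices$start[w], slices$end[w])
    low <- if (is.null(tensor_b)) {
      lofc(sub)
    } else {
      cross_band_lofc(sub, window_tensor(tensor_b, slices$start[w],
                                         slices$end[w]),
                      mode = mode, ratio = ratio)
    }
    mats[[w]] <- if (order == "high") suppressWarnings(hofc(low)) else low
  }
  structure(list(scheme = scheme, band = tensor$band$name,
                 band_b = if (is.null(tensor_b)) NULL else
                   tensor_b$band$name,
                 order = order, matrices = mats,
                 window_starts_s = slices$start_s),
            class = "network_series")
}

# restrict a tensor to a window given in valid-range-relative samples
window_tensor <- function(tensor, start, end) {
  off <- tensor$valid[1] - 1L
  structure(list(band = tensor$band, fs = tensor$fs,
                 phases = tensor$phases, valid = c(off + start, off + end),
                 channel_labels = tensor$channel_labels),
            class = "band_phase_tensor")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("<network_series %s-order [%s]: %d windows of %g s>\n",
              x$order,
              if (is.null(x$band_b)) x$band else
                paste(x$band, x$band_b, sep = "-"),
              length(x$matrices), x$scheme$length_s))
  invisible(x)
}

#' Default anatomical module partition
#'
#' Left/right homologous pairs of the 8-channel montage: frontal {F3, F4},
#' central {C3, C4}, temporal {T3, T4}, occipital {O1, O2}.
#'
#' @return Named character vector mapping channel -> module id.
#' @export
default_partition <- function() {
  c(F3 = "frontal", F4 = "frontal", C3 = "central", C4 = "central",
    T3 = "temporal", T4 = "temporal", O1 = "occipital", O2 = "occipital")
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (kappa_is / k_i)^2`, with `kappa_is` node i's summed
#' weight into module s and `k_i` its total strength; `PC_i = 0` when
#' `k_i = 0`. High values mean strength spread across modules
#' (integration); low values mean strength concentrated within the node's
#' own module (segregation).
#'
#' @param W Prepared nonnegative weight matrix with labeled rows.
#' @param partition Named vector channel -> module (default
#'   [default_partition()]); must cover all nodes, >= 2 modules.
#' @return List with `pc` (per-node values) and `mean` (network mean).
#' @export
participation <- function(W, partition = default_partition()) {
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(W)))
  if (!all(labels %in% names(partition))) {
    stop("partition does not cover all nodes", call. = FALSE)
  }
  mods <- partition[labels]
  if (length(unique(mods)) < 2L) stop("need >= 2 modules", call. = FALSE)
  k <- rowSums(W)
  pc <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    if (k[i] == 0) next
    kappa <- tapply(W[i, ], mods, sum)
    pc[i] <- 1 - sum((kappa / k[i])^2)
  }
  names(pc) <- labels
  list(pc = pc, mean = mean(pc))
}

#' Per-window participation features of a network series
#'
#' @param series A [dynamic_networks()] result.
#' @param partition Module partition.
#' @param mode Weight-preparation mode for high-order windows.
#' @return Windows x nodes matrix of participation coefficients.
#' @export
participation_series <- function(series, partition = default_partition(),
                                 mode = "clip") {
  stopifnot(inherits(series, "network_series"))
  t(vapply(series$matrices, function(m) {
    participation(prepare_weights(m, mode), partition)$pc
  }, numeric(nrow(series$matrices[[1]]$W))))
}

#' Classify windows into integration/segregation states
#'
#' K-means (k = 2, Euclidean, best of `replicates` seeded restarts by
#' within-cluster sum of squares) on per-window participation-coefficient
#' feature vectors. The cluster with the higher mean network-mean PC is
#' labeled 1 (integration), the other 0 (segregation).
#'
#' @param features Windows x nodes matrix of participation coefficients
#'   (or a windows-length numeric vector of network means).
#' @param k Number of states (fixed at 2).
#' @param replicates Number of K-means restarts (default 50).
#' @param seed Integer seed; fixes the labeling bit-for-bit.
#' @return A `state_sequence`: integer vector of 0/1 labels with attribute
#'   `cluster_means` (mean network PC per state).
#' @export
classify_states <- function(features, k = 2L, replicates = 50L, seed = 1L) {
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  if (nrow(features) < 2L) stop("need >= 2 windows", call. = FALSE)
  if (nrow(unique(features)) < k) {
    stop("degenerate clustering: fewer distinct feature vectors than states",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(features, centers = k, nstart = replicates)
  mean_pc <- tapply(rowMeans(features), km$cluster, mean)
  integration_cluster <- as.integer(names(which.max(mean_pc)))
  labels <- as.integer(km$cluster == integration_cluster)
  structure(labels, cluster_means = as.numeric(mean_pc),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence: %d windows, %.0f%% integration>\n",
              length(x), 100 * mean(unclass(x))))
  invisible(x)
}

#' State entropy of an integration/segregation sequence
#'
#' Normalized Shannon entropy of the four consecutive-window transition
#' pairs (00, 01, 10, 11): `SE = -(1/log 4) * sum_i p_i log p_i` with
#' `0 log 0 = 0`. 0 means a single pair type (rigid dynamics), 1 a uniform
#' pair distribution (maximally variable transitions). Invariant to the
#' global relabeling 0 <-> 1.
#'
#' @param labels Binary (0/1) label sequence, length >= 2 (a
#'   [classify_states()] result or plain vector).
#' @return Scalar in `[0, 1]`.
#' @examples
#' state_entropy(rep(1, 10))        # 0
#' state_entropy(c(0, 0, 1, 1, 0, 1, 0, 0, 1)) # mixed
#' @export
state_entropy <- function(labels) {
  labels <- as.integer(unclass(labels))
  if (length(labels) < 2L) stop("need >= 2 labels", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  n <- length(labels)
  pairs <- 2L * labels[-n] + labels[-1L]   # 0..3 <-> 00, 01, 10, 11
  p <- tabulate(pairs + 1L, nbins = 4L) / (n - 1L)
  p <- p[p > 0]
  -sum(p * log(p)) / log(4)
}
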