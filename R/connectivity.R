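#' Phase-locking value between two phase series
#'
#' The modulus of the time-averaged unit phasor of the phase difference,
#' `|mean(exp(i (phi_u - phi_v)))|`: 1 for perfect locking, ~0 for no
#' consistent phase relation. Invariant to a common phase offset.
#'
#' @param phase_u,phase_v Numeric phase vectors (radians), equal length
#'   `N >= 2`, sample-aligned.
#' @return Scalar in `[0, 1]`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' plv(2 * pi * 10 * t, 2 * pi * 10 * t + pi / 3) # constant offset -> 1
#' @export
plv <- function(phase_u, phase_v) {
  if (length(phase_u) != length(phase_v)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (length(phase_u) < 2L) stop("need N >= 2 samples", call. = FALSE)
  Mod(mean(exp(1i * (phase_u - phase_v))))
}

# n:m generalization: |mean(exp(i (n phi_u - m phi_v)))|
plv_nm <- function(phase_u, phase_v, n = 1L, m = 1L) {
  plv(n * phase_u, m * phase_v)
}

#' Connectivity matrix container
#'
#' @param W Square numeric weight matrix.
#' @param order `"low"` (PLV) or `"high"` (correlation of connectivity
#'   profiles).
#' @param scope `"within"` (single band) or `"between"` (band pair).
#' @param band,band_b Band name(s); `band_b` only for `scope = "between"`.
#' @param node_labels Channel labels.
#' @return A `connectivity_matrix` object.
#' @keywords internal
#' @export
connectivity_matrix <- function(W, order, scope, band, band_b = NULL,
                                node_labels = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W),
            order %in% c("low", "high"), scope %in% c("within", "between"))
  if (is.null(node_labels)) node_labels <- rownames(W)
  if (is.null(node_labels)) node_labels <- paste0("ch", seq_len(nrow(W)))
  dimnames(W) <- list(node_labels, node_labels)
  structure(list(W = W, order = order, scope = scope, band = band,
                 band_b = band_b, node_labels = node_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  sc <- if (x$scope == "within") x$band else paste(x$band, x$band_b, sep = "-")
  cat(sprintf("<connectivity_matrix %s-order %s [%s]: %d nodes>\n",
              x$order, x$scope, sc, nrow(x$W)))
  print(round(x$W, 3))
  invisible(x)
}

#' @describeIn connectivity_matrix Long edge-list view (upper triangle for
#'   symmetric matrices, all ordered pairs for band-pair matrices).
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @export
as_tibble.connectivity_matrix <- function(x, ...) {
  lab <- x$node_labels
  if (x$scope == "within") {
    idx <- which(upper.tri(x$W), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_along(lab), col = seq_along(lab)))
  }
  tibble::tibble(
    band = x$band,
    band_b = if (is.null(x$band_b)) NA_character_ else x$band_b,
    order = x$order,
    from = lab[idx[, 1]],
    to = lab[idx[, 2]],
    edge = paste(lab[idx[, 1]], lab[idx[, 2]], sep = "-"),
    weight = x$W[idx]
  )
}

# PLV matrix between the rows of two phase matrices (vectorized):
# |Z_a %*% Conj(t(Z_b))| / N with Z = exp(i * phases)
plv_matrix <- function(pa, pb = NULL) {
  za <- exp(1i * pa)
  zb <- if (is.null(pb)) za else exp(1i * pb)
  Mod(za %*% Conj(t(zb))) / ncol(pa)
}

#' Low-order functional connectivity (within-band PLV network)
#'
#' Static pairwise PLV between all channel pairs over the tensor's full
#' valid range. Symmetric, entries in `[0, 1]`, diagonal fixed at 1 (never
#' used by the graph metrics, which zero it during weight preparation).
#'
#' @param tensor A [band_phase_tensor()], >= 2 channels.
#' @return A [connectivity_matrix()] with `order = "low"`,
#'   `scope = "within"`.
#' @export
lofc <- function(tensor) {
  stopifnot(inherits(tensor, "band_phase_tensor"))
  p <- valid_phases(tensor)
  if (nrow(p) < 2L) stop("need >= 2 channels", call. = FALSE)
  W <- plv_matrix(p)
  W <- (W + t(W)) / 2          # enforce exact symmetry
  W[W > 1] <- 1                # guard rounding
  diag(W) <- 1
  connectivity_matrix(W, "low", "within", tensor$band$name,
                      node_labels = tensor$channel_labels)
}

#' High-order functional connectivity ("correlation of correlations")
#'
#' Edge (i, j) is the Pearson correlation between the connectivity profiles
#' (columns i and j) of a low-order matrix, after removing the
#' self-connection terms — rows i and j are deleted from both columns — and
#' Fisher z-transforming each column. Entries are clipped to
#' `1 - 1e-12` in absolute value before `atanh` so z stays finite.
#'
#' A reduced column with zero variance makes the correlation undefined; the
#' affected entry is set to 0 and a degenerate-edge warning is raised, so
#' downstream graph metrics stay defined.
#'
#' @param lofc_in A low-order [connectivity_matrix()] (within-band or
#'   band-pair), size n >= 4.
#' @return A [connectivity_matrix()] with `order = "high"`: symmetric,
#'   entries in `[-1, 1]`, zero diagonal.
#' @export
hofc <- function(lofc_in) {
  stopifnot(inherits(lofc_in, "connectivity_matrix"))
  if (lofc_in$order != "low") stop("hofc expects a low-order matrix",
                                   call. = FALSE)
  W <- lofc_in$W
  n <- nrow(W)
  if (n < 4L) stop("hofc needs n >= 4 nodes", call. = FALSE)
  eps <- 1e-12
  H <- matrix(0, n, n)
  degenerate <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      ci <- W[keep, i]
      cj <- W[keep, j]
      ci <- pmin(pmax(ci, -(1 - eps)), 1 - eps)
      cj <- pmin(pmax(cj, -(1 - eps)), 1 - eps)
      zi <- atanh(ci)
      zj <- atanh(cj)
      if (stats::sd(zi) == 0 || stats::sd(zj) == 0) {
        H[i, j] <- H[j, i] <- 0
        degenerate <- c(degenerate,
                        paste(lofc_in$node_labels[i], lofc_in$node_labels[j],
                              sep = "-"))
      } else {
        H[i, j] <- H[j, i] <- stats::cor(zi, zj)
      }
    }
  }
  if (length(degenerate) > 0) {
    warning(sprintf("degenerate HOFC edge(s) set to 0: %s",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  connectivity_matrix(H, "high", lofc_in$scope, lofc_in$band, lofc_in$band_b,
                      node_labels = lofc_in$node_labels)
}

#' Between-frequency low-order connectivity
#'
#' PLV between the instantaneous phases of band a on channel i and band b on
#' channel j, for all ordered channel pairs including i = j (the
#' same-channel cross-frequency case). The default is the literal 1:1 phase
#' difference; `mode = "nm"` uses the n:m generalization
#' `|mean(exp(i (n phi_a - m phi_b)))|` with the ratio taken from the
#' rounded band-center ratio unless given.
#'
#' @param tensor_a,tensor_b [band_phase_tensor()]s of two different bands,
#'   same channels and valid range.
#' @param mode `"one_to_one"` (default) or `"nm"`.
#' @param ratio Optional integer `c(n, m)` for `mode = "nm"`.
#' @return A [connectivity_matrix()], `order = "low"`, `scope = "between"`;
#'   rows index channels in band a, columns channels in band b; not
#'   necessarily symmetric.
#' @export
cross_band_lofc <- function(tensor_a, tensor_b,
                            mode = c("one_to_one", "nm"), ratio = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor_a, "band_phase_tensor"),
            inherits(tensor_b, "band_phase_tensor"))
  if (!identical(tensor_a$channel_labels, tensor_b$channel_labels)) {
    stop("channel mismatch between band tensors", call. = FALSE)
  }
  if (!identical(tensor_a$valid, tensor_b$valid)) {
    stop("valid ranges differ between band tensors", call. = FALSE)
  }
  if (tensor_a$band$name == tensor_b$band$name) {
    stop("cross_band_lofc needs two different bands", call. = FALSE)
  }
  pa <- valid_phases(tensor_a)
  pb <- valid_phases(tensor_b)
  if (mode == "nm") {
    if (is.null(ratio)) {
      fa <- band_center(tensor_a$band)
      fb <- band_center(tensor_b$band)
      # phi_b advances fb/fa times faster; lock n*phi_a ~ m*phi_b with
      # n/m ~ fb/fa reduced to small integers
      r <- round(max(fa, fb) / min(fa, fb))
      ratio <- if (fb >= fa) c(r, 1L) else c(1L, r)
    }
    pa <- ratio[1] * pa
    pb <- ratio[2] * pb
  }
  W <- plv_matrix(pa, pb)
  W[W > 1] <- 1
  connectivity_matrix(W, "low", "between", tensor_a$band$name,
                      tensor_b$band$name,
                      node_labels = tensor_a$channel_labels)
}

#' Supra-adjacency matrix over frequency bands
#'
#' Block matrix of size (B x C) x (B x C): diagonal blocks are the
#' within-band low-order PLV matrices; off-diagonal block (a, b) holds the
#' band-pair matrix for (a, b) and block (b, a) its transpose, making S
#' symmetric. The same assembly applies verbatim to high-order blocks.
#'
#' @param within Named list of within-band [connectivity_matrix()]s (one per
#'   band, in band order).
#' @param between Named list of band-pair [connectivity_matrix()]s, names
#'   `"a|b"` for each unordered band pair (a before b in band order).
#' @return A `supra_adjacency`: list with `S`, `bands` (names), `node_labels`
#'   and `block_index`.
#' @export
assemble_supra <- function(within, between) {
  bands <- names(within)
  stopifnot(length(bands) >= 2L)
  C <- nrow(within[[1]]$W)
  labels <- within[[1]]$node_labels
  for (w in within) {
    stopifnot(inherits(w, "connectivity_matrix"),
              identical(w$node_labels, labels))
  }
  B <- length(bands)
  S <- matrix(0, B * C, B * C)
  block <- function(k) ((k - 1) * C + 1):(k * C)
  idx <- list()
  for (a in seq_len(B)) S[block(a), block(a)] <- within[[a]]$W
  pr <- band_pairs(stats::setNames(as.list(bands), bands))
  for (r in seq_len(nrow(pr))) {
    key <- paste(pr$band_a[r], pr$band_b[r], sep = "|")
    bm <- between[[key]]
    if (is.null(bm)) stop(sprintf("missing between-band block '%s'", key),
                          call. = FALSE)
    stopifnot(identical(bm$node_labels, labels))
    a <- match(pr$band_a[r], bands)
    b <- match(pr$band_b[r], bands)
    S[block(a), block(b)] <- bm$W
    S[block(b), block(a)] <- t(bm$W)
    idx[[key]] <- c(a, b)
  }
  dimnames(S) <- rep(list(paste(rep(bands, each = C), rep(labels, B),
                                sep = ":")), 2)
  structure(list(S = S, bands = bands, node_labels = labels,
                 block_index = idx),
            class = "supra_adjacency")
}

#' @export
print.supra_adjacency <- function(x, ...) {
  cat(sprintf("<supra_adjacency: %d bands x %d channels = %d x %d>\n",
              length(x$bands), length(x$node_labels),
              nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Cross-band global coordination metric
#'
#' For each band pair, the arithmetic mean of all entries of its
#' off-diagonal block; the overall metric is the arithmetic mean over all
#' off-diagonal-block entries. Higher values indicate stronger
#' between-frequency coordination.
#'
#' @param supra A [assemble_supra()] result.
#' @return A tibble with one row per band pair (`band_a`, `band_b`,
#'   `global_metric`) plus attribute-free final row `"overall"` in column
#'   `pair`.
#' @export
cross_band_global <- function(supra) {
  stopifnot(inherits(supra, "supra_adjacency"))
  C <- length(supra$node_labels)
  block <- function(k) ((k - 1) * C + 1):(k * C)
  rows <- lapply(names(supra$block_index), function(key) {
    ab <- supra$block_index[[key]]
    tibble::tibble(
      pair = sub("\\|", "-", key),
      band_a = supra$bands[ab[1]],
      band_b = supra$bands[ab[2]],
      global_metric = mean(supra$S[block(ab[1]), block(ab[2])])
    )
  })
  out <- dplyr::bind_rows(rows)
  overall <- mean(out$global_metric)  # equal-size blocks: mean of block means
  dplyr::bind_rows(out, tibble::tibble(pair = "overall", band_a = NA,
                                       band_b = NA,
                                       global_metric = overall))
}
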