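#' Prepare connectivity weights for graph analysis
#'
#' Zeroes the diagonal and maps weights into `[0, 1]`: low-order PLV weights
#' pass through unchanged; high-order (signed correlation) weights have
#' negatives clipped to 0 (default) or replaced by their absolute value.
#'
#' @param M A symmetric [connectivity_matrix()] or plain symmetric matrix.
#' @param mode `"clip"` (negatives -> 0, default) or `"absolute"`.
#' @return Nonnegative symmetric weight matrix with zero diagonal.
#' @export
prepare_weights <- function(M, mode = c("clip", "absolute")) {
  mode <- match.arg(mode)
  W <- if (inherits(M, "connectivity_matrix")) M$W else M
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(abs(W - t(W)) > 1e-10)) {
    stop("prepare_weights expects a symmetric matrix", call. = FALSE)
  }
  W <- (W + t(W)) / 2
  W <- if (mode == "clip") pmax(W, 0) else abs(W)
  diag(W) <- 0
  W
}

#' All-pairs shortest-path length matrix
#'
#' Connection lengths are inverse weights, `l_ij = 1/w_ij` (no edge where
#' `w = 0`); distances are weighted shortest paths, `+Inf` for unreachable
#' pairs. The alternative mapping `l = -log(w)` is available for audit.
#'
#' @param W Prepared nonnegative weight matrix (see [prepare_weights()]).
#' @param length_map `"inverse"` (default) or `"neglog"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_paths <- function(W, length_map = c("inverse", "neglog")) {
  length_map <- match.arg(length_map)
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  pos <- W > 0
  L[pos] <- if (length_map == "inverse") 1 / W[pos] else -log(W[pos])
  diag(L) <- 0
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(L) & L > 0, L, 0), mode = "undirected",
    weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  D
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the geometric-mean triangle intensity,
#' `CC_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` with `k_i`
#' the binary degree; nodes with degree < 2 contribute 0. For weights in
#' `[0, 1]` the result lies in `[0, 1]`; a complete unit-weight graph gives
#' 1 and any triangle-free graph 0.
#'
#' @param W Prepared nonnegative weight matrix.
#' @return Scalar clustering coefficient.
#' @export
clustering_coefficient <- function(W) {
  n <- nrow(W)
  if (n < 3L) return(0)
  W3 <- W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)       # 2 x sum over unordered (j, h)
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(cc)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs. If any pair is
#' unreachable the result is `+Inf`; the mean over finite pairs is attached
#' as attribute `finite_mean` together with a `disconnected` flag.
#'
#' @param D Distance matrix from [shortest_paths()].
#' @return Scalar (possibly `Inf`) with attributes `finite_mean` and
#'   `disconnected`.
#' @export
characteristic_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  disconnected <- any(!is.finite(off))
  cpl <- mean(off)
  structure(cpl,
            finite_mean = if (any(is.finite(off)))
              mean(off[is.finite(off)]) else Inf,
            disconnected = disconnected)
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over ordered node pairs, with
#' `1/Inf = 0`; handles disconnected graphs natively.
#'
#' @param D Distance matrix from [shortest_paths()].
#' @return Scalar in `[0, 1]` for weights in `[0, 1]`.
#' @export
global_efficiency <- function(D) {
  off <- D[row(D) != col(D)]
  if (length(off) == 0L) return(0)
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Weighted local efficiency
#'
#' Mean over nodes of the efficiency of each node's neighborhood subgraph:
#' `LE_i = sum_{j != h in N_i} (w_ij w_ih / d_jh(N_i))^(1/3) /
#' (k_i (k_i - 1))`, where `d_jh(N_i)` is the shortest-path distance between
#' neighbors j and h within the subgraph induced by `N_i` (lengths = inverse
#' weights). Nodes with fewer than 2 neighbors contribute 0.
#'
#' @param W Prepared nonnegative weight matrix.
#' @param length_map Passed to [shortest_paths()] for the neighborhood
#'   subgraphs.
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(W, length_map = "inverse") {
  n <- nrow(W)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    Dsub <- shortest_paths(sub, length_map = length_map)
    acc <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j == h) next
        if (is.finite(Dsub[j, h]) && Dsub[j, h] > 0) {
          acc <- acc + (W[i, nb[j]] * W[i, nb[h]] / Dsub[j, h])^(1 / 3)
        }
      }
    }
    le[i] <- acc / (k * (k - 1))
  }
  mean(le)
}

#' All four weighted graph metrics of a network
#'
#' Composition of [prepare_weights()], [shortest_paths()],
#' [clustering_coefficient()], [characteristic_path_length()],
#' [global_efficiency()] and [local_efficiency()].
#'
#' @param M A symmetric [connectivity_matrix()] or plain matrix.
#' @param mode Weight-preparation mode (see [prepare_weights()]).
#' @param length_map Weight-to-length mapping (see [shortest_paths()]).
#' @return One-row tibble: `cc`, `cpl`, `ge`, `le`, `cpl_finite`,
#'   `disconnected`, plus `band` and `order` metadata when `M` is a
#'   [connectivity_matrix()], and the `mode` used.
#' @export
metric_set <- function(M, mode = c("clip", "absolute"),
                       length_map = c("inverse", "neglog")) {
  mode <- match.arg(mode)
  length_map <- match.arg(length_map)
  W <- prepare_weights(M, mode)
  D <- shortest_paths(W, length_map)
  cpl_val <- characteristic_path_length(D)
  tibble::tibble(
    band = if (inherits(M, "connectivity_matrix")) M$band else NA_character_,
    order = if (inherits(M, "connectivity_matrix")) M$order else NA_character_,
    mode = mode,
    cc = clustering_coefficient(W),
    cpl = as.numeric(cpl_val),
    cpl_finite = attr(cpl_val, "finite_mean"),
    disconnected = attr(cpl_val, "disconnected"),
    ge = global_efficiency(D),
    le = local_efficiency(W, length_map)
  )
}
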