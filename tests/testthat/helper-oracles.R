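# Independent brute-force oracles used across the suite. These are written
# as plain loops / textbook formulas, deliberately sharing no code with the
# package implementations they check.

# unwrap a wrapped phase sequence by accumulating principal-value increments
unwrap_phase <- function(p) {
  cumsum(c(p[1], Arg(exp(1i * diff(p)))))
}

# random symmetric weight matrix with zero diagonal, weights in (0, 1)
rand_weight_matrix <- function(n, density = 0.7, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) W[i, j] <- W[j, i] <- runif(1, 0.05, 0.99)
    }
  }
  W
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/w
oracle_shortest_paths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  }
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# weighted clustering coefficient by explicit triplet enumeration
oracle_cc <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        acc <- acc + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
      }
    }
    vals[i] <- acc / (k * (k - 1))
  }
  mean(vals)
}

oracle_cpl <- function(D) {
  n <- nrow(D)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) acc <- acc + D[i, j]
  acc / (n * (n - 1))
}

oracle_ge <- function(D) {
  n <- nrow(D)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) acc <- acc + 1 / D[i, j]
    }
  }
  acc / (n * (n - 1))
}

# local efficiency by explicit neighborhood extraction + Floyd-Warshall
oracle_le <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    Dsub <- oracle_shortest_paths(W[nb, nb, drop = FALSE])
    acc <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j != h && is.finite(Dsub[j, h]) && Dsub[j, h] > 0) {
          acc <- acc + (W[i, nb[j]] * W[i, nb[h]] / Dsub[j, h])^(1 / 3)
        }
      }
    }
    vals[i] <- acc / (k * (k - 1))
  }
  mean(vals)
}

# high-order network by explicit loops: row deletion, clip, atanh,
# textbook Pearson correlation
oracle_hofc <- function(W) {
  n <- nrow(W)
  eps <- 1e-12
  H <- matrix(0, n, n)
  pearson <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    if (den == 0) return(NA_real_)
    num / den
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- numeric(0)
      cj <- numeric(0)
      for (r in seq_len(n)) {
        if (r == i || r == j) next
        ci <- c(ci, W[r, i])
        cj <- c(cj, W[r, j])
      }
      ci[ci > 1 - eps] <- 1 - eps
      ci[ci < -(1 - eps)] <- -(1 - eps)
      cj[cj > 1 - eps] <- 1 - eps
      cj[cj < -(1 - eps)] <- -(1 - eps)
      r <- pearson(atanh(ci), atanh(cj))
      H[i, j] <- if (is.na(r)) 0 else r
    }
  }
  H
}

# Benjamini-Hochberg step-up by direct rule evaluation
oracle_bh <- function(p, q_star) {
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), mask = logical(0)))
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (j in seq_len(m)) {
    adj[j] <- min(1, min(m * ps[j:m] / (j:m)))
  }
  q <- numeric(m)
  q[ord] <- adj
  # step-up rejection: largest k with p_(k) <= k q*/m, reject 1..k
  k <- 0
  for (j in seq_len(m)) if (ps[j] <= j * q_star / m) k <- j
  mask <- logical(m)
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  list(q = q, mask = mask)
}

# small helper: quick single-band truth for simulation-based tests
quick_truth <- function(band = band_spec("alpha", 8, 13), n_channels = 2L,
                        K = NULL, fs = 128, dur_s = 15, sigma = 1.5,
                        noise_amp = 0.3, groups = c(A = 2L, B = 2L),
                        linkages = list(), seed = 1L, ...) {
  bands <- stats::setNames(list(band), band$name)
  coupling <- list()
  if (!is.null(K)) {
    coupling <- stats::setNames(
      lapply(names(groups), function(g)
        stats::setNames(list(K), band$name)),
      names(groups))
  }
  synthetic_truth(bands = bands, groups = groups, coupling = coupling,
                  fs = fs, dur_s = dur_s, sigma = sigma,
                  noise_amp = noise_amp, n_channels = n_channels,
                  linkages = linkages, seed = seed, ...)
}

# subject-level PLV for one edge of a single-band truth
subject_plv <- function(truth, group, seed, band = truth$bands[[1]],
                        trim_s = 1) {
  rec <- simulate_subject(truth, group, seed)
  L <- lofc(band_phase_tensor(rec, band, trim_s = trim_s))
  L$W
}
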