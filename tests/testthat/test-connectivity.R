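toy_tensor <- function(phases, fs = 100, band = band_spec("alpha", 8, 13),
                       labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(phases)))
  rownames(phases) <- labels
  structure(list(band = band, fs = fs, phases = phases,
                 valid = c(1L, ncol(phases)), channel_labels = labels),
            class = "band_phase_tensor")
}

test_that("plv closed forms: identity, constant offset, cancelling phasors", {
  p <- runif(1000, -pi, pi)
  expect_equal(plv(p, p), 1)
  expect_equal(plv(p, p - pi / 3), 1)
  n <- 400
  diffs <- rep(c(0, pi / 2, pi, 3 * pi / 2), each = n / 4)
  expect_equal(plv(diffs, rep(0, n)), 0, tolerance = 1e-12)
  expect_error(plv(p, p[-1]), "equal length")
  expect_error(plv(1, 2), "N >= 2")
})

test_that("plv is invariant to a global phase constant on both inputs", {
  set.seed(1)
  for (r in 1:5) {
    pu <- cumsum(rnorm(500, 0.1))
    pv <- cumsum(rnorm(500, 0.1))
    c0 <- runif(1, -10, 10)
    expect_equal(plv(pu + c0, pv + c0), plv(pu, pv), tolerance = 1e-12)
  }
})

test_that("lofc: shared phase, independent null, permutation equivariance", {
  p <- matrix(rep(cumsum(rnorm(500, 0.2)), 3), 3, byrow = TRUE)
  L <- lofc(toy_tensor(p))
  expect_true(all(L$W == 1))

  set.seed(7)
  n <- 1e5
  pr <- matrix(runif(4 * n, -pi, pi), 4)
  Lr <- lofc(toy_tensor(pr))
  expect_lt(max(Lr$W[upper.tri(Lr$W)]), 0.02)

  set.seed(8)
  pm <- matrix(cumsum(rnorm(5 * 300, 0.05)), 5)
  perm <- c(4, 2, 5, 1, 3)
  La <- lofc(toy_tensor(pm))
  Lb <- lofc(toy_tensor(pm[perm, ], labels = paste0("ch", perm)))
  expect_equal(Lb$W, La$W[perm, perm], ignore_attr = TRUE, tolerance = 1e-12)

  # symmetry and range invariants
  expect_true(isSymmetric(La$W))
  expect_true(all(La$W >= 0 & La$W <= 1))
})

test_that("hofc matches closed-form cases and the declared degenerate policy", {
  # two columns identical after row removal -> edge 1
  W <- rand_weight_matrix(6, density = 1, seed = 2)
  diag(W) <- 1
  W[, 2] <- W[, 1]
  W[2, ] <- W[1, ]  # keep symmetric; columns 1, 2 identical off-diagonal
  W[1, 2] <- W[2, 1] <- W[1, 2]
  L <- connectivity_matrix(W, "low", "within", "alpha")
  H <- hofc(L)
  expect_equal(H$W[1, 2], 1, tolerance = 1e-12)

  # constant off-diagonal entries -> zero-variance columns -> 0 + warning
  Wc <- matrix(0.5, 5, 5); diag(Wc) <- 1
  Lc <- connectivity_matrix(Wc, "low", "within", "alpha")
  expect_warning(Hc <- hofc(Lc), "degenerate")
  expect_true(all(Hc$W == 0))

  expect_error(hofc(connectivity_matrix(matrix(1, 3, 3), "low", "within",
                                        "a")), "n >= 4")
})

test_that("hofc equals the brute-force oracle on seeded random matrices", {
  for (s in 1:25) {
    n <- sample(5:12, 1)
    W <- rand_weight_matrix(n, density = 1, seed = 100 + s)
    diag(W) <- 1
    L <- connectivity_matrix(W, "low", "within", "alpha")
    H <- hofc(L)
    expect_lt(max(abs(H$W - oracle_hofc(W))), 1e-12)
    expect_true(isSymmetric(H$W))
    expect_true(all(abs(H$W) <= 1))
    expect_true(all(diag(H$W) == 0))
  }
})

test_that("cross-band PLV: identical phases, independent drift, n:m mode", {
  set.seed(5)
  p <- matrix(rep(cumsum(rnorm(500, 0.05)), 4), 4, byrow = TRUE)
  ta <- toy_tensor(p, band = band_spec("theta", 4, 8))
  tb <- toy_tensor(p, band = band_spec("alpha", 8, 13))
  X <- cross_band_lofc(ta, tb)  # second band a relabeled copy, shared phase
  expect_true(all(abs(X$W - 1) < 1e-12))

  set.seed(6)
  n <- 1e5
  pa <- matrix(runif(2 * n, -pi, pi), 2)
  pb <- matrix(runif(2 * n, -pi, pi), 2)
  Xn <- cross_band_lofc(toy_tensor(pa, band = band_spec("theta", 4, 8)),
                        toy_tensor(pb, band = band_spec("alpha", 8, 13)))
  expect_lt(max(Xn$W), 0.05)

  # exact 2:1 harmonic: invisible to 1:1 PLV, locked under n:m mode
  base <- cumsum(rnorm(2000, 0.06, 0.01))
  pa2 <- rbind(base, cumsum(rnorm(2000, 0.05)))
  pb2 <- rbind(2 * base, cumsum(rnorm(2000, 0.1)))
  ta2 <- toy_tensor(pa2, band = band_spec("theta", 4, 8))
  tb2 <- toy_tensor(pb2, band = band_spec("alpha", 8, 13))
  Xnm <- cross_band_lofc(ta2, tb2, mode = "nm", ratio = c(2, 1))
  expect_gt(Xnm$W[1, 1], 0.99)

  expect_error(cross_band_lofc(ta, ta), "different bands")
})

test_that("supra-adjacency assembly is symmetric with correct blocks", {
  bands <- names(default_bands())
  C <- 8
  within <- lapply(bands, function(b) {
    W <- matrix(1, C, C)
    connectivity_matrix(W, "low", "within", b,
                        node_labels = default_channels())
  })
  names(within) <- bands
  pr <- band_pairs()
  between <- list()
  for (r in seq_len(nrow(pr))) {
    key <- paste(pr$band_a[r], pr$band_b[r], sep = "|")
    between[[key]] <- connectivity_matrix(
      matrix(0.5, C, C), "low", "between", pr$band_a[r], pr$band_b[r],
      node_labels = default_channels())
  }
  S <- assemble_supra(within, between)
  expect_equal(dim(S$S), c(32, 32))
  expect_identical(S$S, t(S$S))
  g <- cross_band_global(S)
  expect_equal(g$global_metric[g$pair != "overall"], rep(0.5, 6))

  between$`delta|theta` <- NULL
  expect_error(assemble_supra(within, between), "missing")
})

test_that("cross-band global metric: direct arithmetic and linear scaling", {
  C <- 8
  bands <- c("delta", "theta")
  mk <- function(W, scope, a, b = NULL)
    connectivity_matrix(W, "low", scope, a, b)
  within <- list(delta = mk(diag(C) * 0 + 1, "within", "delta"),
                 theta = mk(diag(C) * 0 + 1, "within", "theta"))
  B <- matrix(0.5, C, C)
  B[1, 1] <- 0.6
  S <- assemble_supra(within, list(`delta|theta` = mk(B, "between", "delta",
                                                      "theta")))
  g <- cross_band_global(S)
  expect_equal(g$global_metric[g$pair == "delta-theta"],
               (63 * 0.5 + 0.6) / 64)

  lam <- 0.3
  S2 <- assemble_supra(within,
                       list(`delta|theta` = mk(lam * B, "between", "delta",
                                               "theta")))
  g2 <- cross_band_global(S2)
  expect_equal(g2$global_metric[g2$pair == "delta-theta"],
               lam * g$global_metric[g$pair == "delta-theta"],
               tolerance = 1e-12)
})
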