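complete_graph <- function(n) {
  W <- matrix(1, n, n); diag(W) <- 0; W
}

chain3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

star_graph <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  W
}

test_that("weight preparation zeroes the diagonal and rectifies negatives", {
  W <- matrix(c(1, 0.7, 0.7, 1), 2)
  expect_equal(prepare_weights(W), matrix(c(0, 0.7, 0.7, 0), 2))
  H <- matrix(c(0, -0.4, -0.4, 0), 2)
  expect_equal(prepare_weights(H, "clip")[1, 2], 0)
  expect_equal(prepare_weights(H, "absolute")[1, 2], 0.4)
  A <- matrix(c(0, 1, 0.2, 0), 2)
  expect_error(prepare_weights(A), "symmetric")
})

test_that("shortest paths follow inverse-weight lengths", {
  D <- shortest_paths(chain3())
  expect_equal(D[1, 2], 1)
  expect_equal(D[2, 3], 1)
  expect_equal(D[1, 3], 2)

  expect_true(all(shortest_paths(complete_graph(5))[upper.tri(diag(5))] == 1))

  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(shortest_paths(W)[1, 2], 2)

  # isolated node -> infinite distance
  W4 <- matrix(0, 3, 3); W4[1, 2] <- W4[2, 1] <- 1
  expect_equal(shortest_paths(W4)[1, 3], Inf)
})

test_that("closed-form metric values: complete, chain, star", {
  expect_equal(clustering_coefficient(complete_graph(6)), 1)
  expect_equal(clustering_coefficient(star_graph(6)), 0)
  expect_equal(local_efficiency(complete_graph(6)), 1)
  expect_equal(local_efficiency(star_graph(6)), 0)

  D <- shortest_paths(chain3())
  expect_equal(as.numeric(characteristic_path_length(D)), 4 / 3)
  expect_equal(global_efficiency(D), 5 / 6)

  Dc <- shortest_paths(complete_graph(4))
  expect_equal(as.numeric(characteristic_path_length(Dc)), 1)
  expect_equal(global_efficiency(Dc), 1)

  # empty graph: no paths at all
  expect_equal(global_efficiency(shortest_paths(matrix(0, 4, 4))), 0)

  # disconnected graph: CPL +Inf with flag, finite-subnetwork mean reported
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  cpl <- characteristic_path_length(shortest_paths(W))
  expect_equal(as.numeric(cpl), Inf)
  expect_true(attr(cpl, "disconnected"))
  expect_equal(attr(cpl, "finite_mean"), 1)
})

test_that("metric_set composes the four metrics with metadata", {
  ms <- metric_set(chain3())
  expect_equal(ms$cc, 0)
  expect_equal(ms$cpl, 4 / 3)
  expect_equal(ms$ge, 5 / 6)
  expect_equal(ms$le, 0)

  msc <- metric_set(complete_graph(5))
  expect_equal(unlist(msc[, c("cc", "cpl", "ge", "le")]),
               c(cc = 1, cpl = 1, ge = 1, le = 1))

  # permutation invariance
  W <- rand_weight_matrix(8, seed = 11)
  perm <- sample(8)
  expect_equal(metric_set(W)[, c("cc", "cpl", "ge", "le")],
               metric_set(W[perm, perm])[, c("cc", "cpl", "ge", "le")],
               tolerance = 1e-12)
})

test_that("all four metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (s in 1:60) {
    n <- sample(5:12, 1)
    W <- rand_weight_matrix(n, density = runif(1, 0.3, 1), seed = 7000 + s)
    D <- shortest_paths(W)
    Do <- oracle_shortest_paths(W)
    expect_lt(max(abs(D - Do)[is.finite(D)]), 1e-10)
    expect_identical(is.finite(D), is.finite(Do))
    expect_lt(abs(clustering_coefficient(W) - oracle_cc(W)), 1e-10)
    if (all(is.finite(Do[row(Do) != col(Do)]))) {
      expect_lt(abs(as.numeric(characteristic_path_length(D)) -
                      oracle_cpl(Do)), 1e-10)
    }
    expect_lt(abs(global_efficiency(D) - oracle_ge(Do)), 1e-10)
    expect_lt(abs(local_efficiency(W) - oracle_le(W)), 1e-10)
  }
})

test_that("metric invariants: ranges, GE*CPL >= 1, GE monotone in edges", {
  for (s in 1:20) {
    W <- rand_weight_matrix(9, density = 0.8, seed = 300 + s)
    D <- shortest_paths(W)
    cc <- clustering_coefficient(W)
    ge <- global_efficiency(D)
    le <- local_efficiency(W)
    cpl <- as.numeric(characteristic_path_length(D))
    expect_true(cc >= 0 && cc <= 1)
    expect_true(ge >= 0 && ge <= 1)
    expect_true(le >= 0 && le <= 1)
    if (is.finite(cpl)) expect_gte(ge * cpl, 1 - 1e-12)

    # raising a zero weight never decreases global efficiency
    zeros <- which(W == 0 & row(W) < col(W))
    if (length(zeros)) {
      W2 <- W
      k <- zeros[1]
      W2[k] <- 0.5
      W2[cbind(col(W)[k], row(W)[k])] <- 0.5
      expect_gte(global_efficiency(shortest_paths(W2)) + 1e-12, ge)
    }
  }
})
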