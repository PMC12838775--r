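test_that("window arithmetic matches the closed-form count", {
  # 300 s at 1000 Hz, 20% overlap: frozen counts for the six lengths
  expected <- c(`0.5` = 749, `1` = 374, `2` = 187, `4` = 93, `6` = 62,
                `8` = 46)
  for (len in names(expected)) {
    sl <- window_slices(300000, 1000, window_scheme(as.numeric(len), 0.2))
    expect_equal(nrow(sl), unname(expected[[len]]))
    expect_equal(sl$start[2] - sl$start[1],
                 round(0.8 * as.numeric(len) * 1000))
    expect_true(all(sl$end <= 300000))
  }
  expect_error(window_slices(7999, 1000, window_scheme(8, 0.2)), "longer")
})

test_that("dynamic networks honor the slice contract and lock constant pairs", {
  base <- cumsum(rnorm(3000, 0.08, 0.02))
  phases <- rbind(base, base + 1.1)
  rownames(phases) <- c("ch1", "ch2")
  tn <- structure(list(band = band_spec("alpha", 8, 13), fs = 100,
                       phases = phases, valid = c(1L, 3000L),
                       channel_labels = c("ch1", "ch2")),
                  class = "band_phase_tensor")
  sch <- window_scheme(2, 0.2)
  series <- dynamic_networks(tn, sch)
  expect_equal(length(series$matrices),
               nrow(window_slices(3000, 100, sch)))
  for (m in series$matrices) expect_equal(m$W[1, 2], 1, tolerance = 1e-12)
})

test_that("a coupling level shift appears across the window boundary", {
  # stationary segment pairs with different phase coupling, concatenated
  set.seed(21)
  n <- 2000
  locked <- cumsum(rnorm(n, 0.1, 0.01))
  seg1 <- rbind(locked, locked + 0.4 + rnorm(n, 0, 0.05))
  seg2 <- rbind(cumsum(rnorm(n, 0.1, 0.3)), cumsum(rnorm(n, 0.1, 0.3)))
  phases <- cbind(seg1, seg2)
  rownames(phases) <- c("ch1", "ch2")
  tn <- structure(list(band = band_spec("alpha", 8, 13), fs = 100,
                       phases = phases, valid = c(1L, 2L * n),
                       channel_labels = c("ch1", "ch2")),
                  class = "band_phase_tensor")
  series <- dynamic_networks(tn, window_scheme(5, 0))
  edge <- vapply(series$matrices, function(m) m$W[1, 2], numeric(1))
  expect_gt(min(edge[1:4]), 0.9)   # fully inside the locked segment
  expect_lt(max(edge[5:8]), 0.6)   # fully inside the unlocked segment
})

test_that("participation coefficient follows the strength-split formula", {
  part <- c(a = "m1", b = "m1", c = "m2", d = "m3", e = "m4", f = "m4")
  # node with all strength inside its own module
  W <- matrix(0, 6, 6, dimnames = list(names(part), names(part)))
  W["a", "b"] <- W["b", "a"] <- 0.8
  expect_equal(participation(W, part)$pc[["a"]], 0)
  # split equally across 2 modules
  W2 <- matrix(0, 6, 6, dimnames = list(names(part), names(part)))
  W2["a", "b"] <- W2["b", "a"] <- 0.5
  W2["a", "c"] <- W2["c", "a"] <- 0.5
  expect_equal(participation(W2, part)$pc[["a"]], 0.5)
  # split equally across 4 modules
  W3 <- matrix(0, 6, 6, dimnames = list(names(part), names(part)))
  for (tgt in c("b", "c", "d", "e")) W3["a", tgt] <- W3[tgt, "a"] <- 0.25
  expect_equal(participation(W3, part)$pc[["a"]], 0.75)
  # isolated node
  expect_equal(participation(matrix(0, 6, 6,
                                    dimnames = list(names(part),
                                                    names(part))),
                             part)$pc[["a"]], 0)
  expect_error(participation(matrix(0, 2, 2), part), "cover")
})

test_that("state classification recovers separated blobs and labels by PC", {
  set.seed(4)
  hi <- matrix(rnorm(40 * 4, mean = 0.8, sd = 0.02), 40)
  lo <- matrix(rnorm(40 * 4, mean = 0.2, sd = 0.02), 40)
  feats <- rbind(hi, lo)[sample(80), ]
  states <- classify_states(feats, seed = 5)
  expect_equal(as.integer(unclass(states)), as.integer(rowMeans(feats) > 0.5))

  # seeded determinism
  s2 <- classify_states(feats, seed = 5)
  expect_identical(unclass(states), unclass(s2))

  # swapping the blobs' PC levels flips the labeling
  flipped <- 1 - feats
  sf <- classify_states(flipped, seed = 5)
  expect_equal(as.integer(unclass(sf)), 1L - as.integer(unclass(states)))

  expect_error(classify_states(matrix(0.5, 10, 4)), "degenerate")
})

test_that("state entropy: closed forms, swap invariance, Bernoulli limit", {
  expect_equal(state_entropy(rep(1, 50)), 0)
  expect_equal(state_entropy(rep(0, 50)), 0)
  # equal counts of all four pairs
  block <- c(0, 0, 1, 1)
  seq4 <- c(rep(block, 25), 0)  # 00,01,11,10 each 25 times
  expect_equal(state_entropy(seq4), 1)
  # alternating labels: pairs 4x"01", 3x"10"
  alt <- rep(c(0, 1), 4)
  expect_equal(state_entropy(alt),
               -(4 / 7 * log(4 / 7) + 3 / 7 * log(3 / 7)) / log(4))
  expect_equal(state_entropy(alt), 0.4926, tolerance = 1e-4)
  # 0 <-> 1 swap invariance on random sequences
  set.seed(10)
  for (r in 1:10) {
    lab <- rbinom(200, 1, runif(1, 0.2, 0.8))
    if (length(unique(lab)) < 2) next
    expect_equal(state_entropy(lab), state_entropy(1 - lab),
                 tolerance = 1e-12)
    se <- state_entropy(lab)
    expect_true(se >= 0 && se <= 1)
  }
  # iid Bernoulli(1/2): SE -> 1
  set.seed(11)
  expect_equal(state_entropy(rbinom(1e4, 1, 0.5)), 1, tolerance = 0.01)
  expect_error(state_entropy(1L), "2 labels")
})

test_that("end-to-end states track a planted integration/segregation schedule", {
  # alternate 10 s segments: global all-to-all coupling (integration:
  # strength spread over both modules) vs dense within-module coupling only
  # (segregation: strength concentrated in the node's own module)
  fs <- 128
  part <- c(F3 = "ant", F4 = "ant", T3 = "ant", C3 = "ant",
            C4 = "post", T4 = "post", O1 = "post", O2 = "post")
  # integration: one globally coupled 8-oscillator population at 10.5 Hz;
  # segregation: two independent 4-oscillator modules at 9 and 12 Hz
  # (cross-module phase differences then precess within every window)
  t_int <- quick_truth(n_channels = 8L, fs = fs, dur_s = 10, sigma = 1.5,
                       K = coupling_matrix(8, t(utils::combn(8, 2)), 8),
                       seed = 31)
  mod_truth <- function(f0) synthetic_truth(
    bands = list(alpha = band_spec("alpha", 8, 13)),
    groups = c(A = 2L, B = 2L),
    coupling = list(A = list(alpha = coupling_matrix(
      4, t(utils::combn(4, 2)), 8))),
    f0 = c(alpha = f0), sigma = 1.5, noise_amp = 0.3,
    fs = fs, dur_s = 10, n_channels = 4L, seed = 31)
  sim_seg <- function(seed) {
    rbind(simulate_subject(mod_truth(9), "A", seed)$data,
          simulate_subject(mod_truth(12), "A", seed + 1)$data)
  }
  x <- cbind(simulate_subject(t_int, "A", 101)$data, sim_seg(102),
             simulate_subject(t_int, "A", 103)$data, sim_seg(104))
  rec <- eeg_recording(x, fs, default_channels())
  tn <- band_phase_tensor(rec, band_spec("alpha", 8, 13), trim_s = 1)
  sch <- window_scheme(2, 0.2)
  series <- dynamic_networks(tn, sch)
  feats <- participation_series(series, part)
  states <- classify_states(feats, seed = 3)
  # schedule per window (valid range starts 1 s in); unambiguous windows
  # lie fully inside one segment, away from the 10/20/30 s boundaries
  starts <- series$window_starts_s + 1
  ends <- starts + sch$length_s
  seg_of <- function(t) floor(t / 10)
  unamb <- seg_of(starts) == seg_of(ends - 1e-9)
  truth_label <- 1 - seg_of(starts) %% 2   # segments 0,2 are integration
  agree <- mean(states[unamb] == truth_label[unamb])
  expect_gte(agree, 0.9)
})
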