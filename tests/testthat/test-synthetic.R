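test_that("truth validation rejects malformed configurations", {
  expect_error(synthetic_truth(groups = c(A = 1L, B = 5L)), ">= 2")
  expect_error(synthetic_truth(fs = 0), "positive")
  bad_K <- matrix(0.1, 8, 8)  # nonzero diagonal
  expect_error(synthetic_truth(
    groups = c(A = 2L, B = 2L),
    coupling = list(A = list(delta = bad_K))), "zero-diagonal")
  expect_error(synthetic_truth(f0 = c(delta = 9, theta = 6, alpha = 10,
                                      beta = 20)), "inside")
  tr <- quick_truth()
  expect_error(simulate_subject(tr, "nope", 1), "unknown group")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  tr <- quick_truth(dur_s = 5)
  r1 <- simulate_subject(tr, "A", 77)
  r2 <- simulate_subject(tr, "A", 77)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_subject(tr, "A", 78)
  expect_false(identical(r1$data, r3$data))
})

test_that("cohort bookkeeping: sizes, labels, seed derivation", {
  tr <- quick_truth(dur_s = 3, groups = c(TD = 3L, ASD = 4L))
  coh <- simulate_cohort(tr)
  expect_length(coh$recordings, 7)
  expect_equal(sum(coh$manifest$group == "TD"), 3)
  expect_equal(sum(coh$manifest$group == "ASD"), 4)
  expect_false(anyDuplicated(coh$manifest$seed) > 0)
  # same truth reproduces the cohort; different base seed changes it
  coh2 <- simulate_cohort(tr)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
  tr2 <- quick_truth(dur_s = 3, groups = c(TD = 3L, ASD = 4L), seed = 2L)
  coh3 <- simulate_cohort(tr2)
  expect_false(identical(coh$recordings[[1]]$data, coh3$recordings[[1]]$data))
  expect_equal(dim(coh3$recordings[[1]]$data), dim(coh$recordings[[1]]$data))
})

test_that("uncoupled channels show near-zero PLV, coupled ones lock", {
  # independent phases: PLV stays well below 0.1 over a long recording
  tr0 <- quick_truth(K = coupling_matrix(2), fs = 250, dur_s = 300,
                     sigma = 3, noise_amp = 0)
  W0 <- subject_plv(tr0, "A", 5)
  expect_lt(W0[1, 2], 0.1)

  # strong Kuramoto coupling phase-locks the pair
  tr1 <- quick_truth(K = coupling_matrix(2, rbind(c(1, 2)), 50), fs = 250,
                     dur_s = 60, sigma = 1, noise_amp = 0.3)
  W1 <- subject_plv(tr1, "A", 5)
  expect_gt(W1[1, 2], 0.8)
})

test_that("empirical PLV is monotone in coupling strength", {
  levels <- c(0, 1.5, 6)
  mean_plv <- vapply(levels, function(k) {
    tr <- quick_truth(K = coupling_matrix(2, rbind(c(1, 2)), k), fs = 128,
                      dur_s = 15, sigma = 1.5)
    mean(vapply(1:10, function(s) subject_plv(tr, "A", 1000 + s)[1, 2],
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_plv) > -0.02))
  expect_gt(mean_plv[3], mean_plv[1] + 0.3)
})

test_that("per-band power concentrates in the generating band", {
  # single-band truths: the matching band-pass captures >= 80% of the
  # total band-passed power
  fs <- 256
  bands <- default_bands()
  for (gen in c("delta", "alpha")) {
    tr <- synthetic_truth(
      bands = bands[gen], groups = c(A = 2L, B = 2L),
      fs = fs, dur_s = 20, n_channels = 2L, noise_amp = 0.2, seed = 3)
    rec <- simulate_subject(tr, "A", 9)
    pw <- vapply(bands, function(b) {
      flt <- bandpass(rec, b)
      mean(flt$data[, (2 * fs):(ncol(flt$data) - 2 * fs)]^2)
    }, numeric(1))
    expect_gt(pw[[gen]] / sum(pw), 0.8)
  }
})

test_that("cross-band linkage plants measurable n:m locking", {
  bands <- list(theta = band_spec("theta", 4, 8),
                alpha = band_spec("alpha", 8, 13))
  lk <- cross_band_linkage("theta", "alpha", 1, 1, strength = 1, n = 2, m = 1)
  tr <- synthetic_truth(bands = bands, groups = c(A = 2L, B = 2L),
                        f0 = c(theta = 6, alpha = 10.5),
                        linkages = list(lk), fs = 128, dur_s = 30,
                        n_channels = 2L, noise_amp = 0.2, sigma = 1, seed = 4)
  rec <- simulate_subject(tr, "A", 12)
  tens <- band_phases(rec, bands, trim_s = 1)
  X <- cross_band_lofc(tens$theta, tens$alpha, mode = "nm", ratio = c(2, 1))
  expect_gt(X$W[1, 1], 0.8)
  # an unlinked channel pair stays unlocked
  expect_lt(X$W[2, 2], 0.4)
})
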