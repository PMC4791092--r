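cardiac <- cardiac_protocol()
liver <- liver_protocol()

test_that("adapts_config validates its constants", {
  cfg <- adapts_config()
  expect_equal(cfg$p1, 4.5)
  expect_equal(cfg$p2, 9)
  expect_error(adapts_config(p1 = 0), "positive")
  expect_error(adapts_config(p2 = 1), "integer")
  expect_error(adapts_config(p2 = 8.5), "integer")
})

test_that("truncate_tes keeps echoes up to the inclusive threshold", {
  # threshold 4.5 * 4 = 18 ms keeps the first seven cardiac echoes
  expect_equal(truncate_tes(cardiac, 4, adapts_config()), 1:7)
  # a long T2* keeps the whole train
  expect_equal(truncate_tes(cardiac, 50, adapts_config()), 1:10)
  # threshold 9 ms keeps four liver echoes
  expect_equal(truncate_tes(liver, 2, adapts_config()), 1:4)
  # inclusive boundary: TE exactly at p1 * t2 is retained
  expect_equal(truncate_tes(cardiac, 5, adapts_config()), 1:9)
  expect_error(truncate_tes(cardiac, 0), "positive")
})

test_that("truncation is monotone in p1", {
  set.seed(3)
  for (i in 1:25) {
    t2i <- runif(1, 0.5, 30)
    p1s <- sort(runif(2, 0.5, 8))
    n1 <- length(truncate_tes(cardiac, t2i, adapts_config(p1 = p1s[1])))
    n2 <- length(truncate_tes(cardiac, t2i, adapts_config(p1 = p1s[2])))
    expect_lte(n1, n2)
  }
})

test_that("noiseless monoexponential input is recovered on both branches", {
  # T2* = 10: threshold 45 ms keeps all 10 echoes >= p2 -> truncation branch
  r10 <- adapts_estimate(noiseless_signal(cardiac, 100, 10))
  expect_equal(r10$branch, "truncation")
  expect_length(r10$kept_te_indices, 10)
  expect_equal(r10$t2, 10, tolerance = 1e-4)

  # T2* = 3: threshold 13.5 ms keeps 5 < 9 -> noise-corrected branch
  r3 <- adapts_estimate(noiseless_signal(cardiac, 100, 3))
  expect_equal(r3$branch, "noise_corrected")
  expect_lt(length(r3$kept_te_indices), 9)
  expect_equal(r3$t2, 3, tolerance = 1e-3 * 3)

  for (t2 in c(2, 6, 20, 40)) {
    r <- adapts_estimate(noiseless_signal(liver, 80, t2))
    expect_equal(r$t2, t2, tolerance = 1e-3 * t2)
  }
})

test_that("branch dichotomy follows the retained echo count", {
  # for the cardiac train with defaults the switch sits at
  # t2_initial = 22.5 / 4.5 = 5 ms
  set.seed(17)
  noise <- sim_noise(n_coils = 6)
  for (t2 in c(2, 4, 8, 15, 30)) {
    sig <- simulate_roi_signal(t2, 100, noise, cardiac, 40)
    r <- adapts_estimate(sig)
    expect_identical(r$branch == "truncation",
                     length(r$kept_te_indices) >= 9)
    # the retained set is a prefix of the echo train
    expect_equal(r$kept_te_indices, seq_along(r$kept_te_indices))
    expect_gt(r$t2, 0)
  }
})

test_that("adapts_estimate is deterministic", {
  set.seed(5)
  sig <- simulate_roi_signal(8, 100, sim_noise(), cardiac, 40)
  r1 <- adapts_estimate(sig)
  r2 <- adapts_estimate(sig)
  expect_identical(r1$t2, r2$t2)
  expect_identical(r1$t2_initial, r2$t2_initial)
  expect_identical(r1$branch, r2$branch)
})

test_that("estimates are invariant to overall signal scale", {
  set.seed(9)
  sig <- simulate_roi_signal(6, 100, sim_noise(), liver, 40)
  scaled <- decay_signal(liver, sig$values * 37.5)
  expect_equal(adapts_estimate(sig)$t2, adapts_estimate(scaled)$t2,
               tolerance = 1e-6)
})

test_that("adapts_estimate rejects unusable input", {
  expect_error(adapts_estimate(decay_signal(echo_protocol(1:3), c(3, 2, 1))),
               "four echoes")
  expect_error(adapts_estimate(decay_signal(cardiac, rep(0, 10))),
               "zero")
})

test_that("forcing p2 above the echo count forces the noise-corrected branch", {
  set.seed(23)
  sig <- simulate_roi_signal(20, 100, sim_noise(), cardiac, 40)
  r <- adapts_estimate(sig, adapts_config(p2 = 11))
  expect_equal(r$branch, "noise_corrected")
})
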