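liver <- liver_protocol()

test_that("noise-free simulation reproduces the exact decay", {
  for (L in c(1, 6, 32)) {
    px <- simulate_pixel(10, 100, coil_noise_model(L, 0), liver)
    expect_equal(px, sqrt(2 * L) * 100 * exp(-liver$tes / 10),
                 tolerance = 1e-12)
  }
})

test_that("zero-signal single-coil magnitudes follow the Rayleigh mean", {
  set.seed(101)
  m <- adapts:::cpp_simulate_pixels(liver$tes, 10, 0, 1, 1L, 20000L)
  expect_equal(mean(m), sqrt(pi / 2), tolerance = 0.01)
})

test_that("zero-signal multi-coil magnitudes follow the noncentral-chi floor", {
  set.seed(103)
  for (L in c(6, 32)) {
    m <- adapts:::cpp_simulate_pixels(liver$tes, 10, 0, 1, as.integer(L),
                                      5000L)
    floor_mean <- sqrt(2) * gamma(L + 0.5) / gamma(L)
    expect_equal(mean(m), floor_mean, tolerance = 0.01)
  }
})

test_that("simulated squared magnitudes satisfy the second-moment identity", {
  # E[RSS^2] = S^2 + 2 L sigma^2 with S the noiseless RSS decay
  set.seed(107)
  L <- 6L; sigma <- 5; t2 <- 10; s0 <- 100
  m <- adapts:::cpp_simulate_pixels(liver$tes, t2, s0, sigma, L, 100000L)
  emp <- rowMeans(m^2)
  expect_equal(emp,
               2 * L * s0^2 * exp(-2 * liver$tes / t2) + 2 * L * sigma^2,
               tolerance = 0.01)
})

test_that("ROI averaging reduces variance by the pixel count", {
  set.seed(109)
  noise <- sim_noise(n_coils = 6)
  single <- replicate(4000, simulate_pixel(10, 100, noise, liver)[1])
  set.seed(110)
  avg <- replicate(1000,
                   simulate_roi_signal(10, 100, noise, liver, 25)$values[1])
  expect_equal(var(avg), var(single) / 25, tolerance = 0.25)
})

test_that("pixels are drawn independently", {
  set.seed(113)
  roi <- simulate_roi_pixels(10, 100, sim_noise(), liver, 2)
  # correlation across repeated draws of two pixels at the first echo
  a <- replicate(3000, {
    r <- adapts:::cpp_simulate_pixels(liver$tes[1:2], 10, 100, 100 / 15,
                                      6L, 2L)
    r[1, ]
  })
  expect_lt(abs(cor(a[1, ], a[2, ])), 0.05)
})

test_that("the ROI mean of pixel draws equals the averaged signal", {
  noise <- sim_noise()
  set.seed(127)
  roi <- simulate_roi_pixels(8, 100, noise, liver, 40)
  set.seed(127)
  sig <- simulate_roi_signal(8, 100, noise, liver, 40)
  expect_identical(rowMeans(roi$pixel_signals), sig$values)
})

test_that("seeded draws are bit-reproducible", {
  noise <- sim_noise(n_coils = 32)
  set.seed(131)
  a <- simulate_pixel(5, 100, noise, liver)
  set.seed(131)
  b <- simulate_pixel(5, 100, noise, liver)
  expect_identical(a, b)
})

test_that("simulation_config validates its fields", {
  expect_error(simulation_config(c(0, 5), liver, seed = 1), "positive")
  expect_error(simulation_config(5, liver, snr = 0, seed = 1), "snr")
  expect_error(simulation_config(5, liver, repetitions = 0, seed = 1),
               "repetitions")
  cfg <- simulation_config(c(5, 10), liver, repetitions = 10, seed = 4)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$s0 / cfg$snr, 100 / 15)
})
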