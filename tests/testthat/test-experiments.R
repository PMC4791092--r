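liver <- liver_protocol()

tiny_cfg <- function(..., t2_grid = c(5, 20), reps = 8) {
  simulation_config(t2_grid, liver, n_coils = 6, roi_pixels = 40,
                    repetitions = reps, seed = 2, ...)
}

test_that("noise-free sweeps have zero bias and zero CI", {
  cfg <- tiny_cfg(snr = Inf)
  r <- run_accuracy_precision_sweep(cfg, estimators = c(
    "adapts", "m2ncm_true_sigma", "truncation_only", "noise_corrected_only"))
  expect_true(all(abs(r$mean_bias) < 0.01))
  expect_true(all(r$ci95 < 0.01))
  expect_true(all(r$n_failed == 0))
})

test_that("sweep output is deterministic given the seed", {
  cfg <- tiny_cfg(t2_grid = c(4, 12), reps = 20)
  r1 <- run_accuracy_precision_sweep(cfg)
  r2 <- run_accuracy_precision_sweep(cfg)
  expect_identical(r1, r2)
})

test_that("a single parameter pair reduces to the accuracy sweep", {
  cfg <- tiny_cfg(reps = 20)
  ps <- run_parameter_sweep(4.5, 9, cfg)
  sw <- run_accuracy_precision_sweep(cfg, estimators = "adapts")
  expect_equal(ps$mean_bias, sw$mean_bias)
  expect_equal(ps$ci95, sw$ci95)
})

test_that("p2 above the echo count reproduces the pure noise-corrected fit", {
  cfg <- tiny_cfg(reps = 20)
  forced <- run_accuracy_precision_sweep(cfg, estimators = "adapts",
                                         adapts = adapts_config(p2 = 11))
  pure <- run_accuracy_precision_sweep(cfg,
                                       estimators = "noise_corrected_only")
  expect_equal(forced$mean_bias, pure$mean_bias)
  expect_equal(forced$ci95, pure$ci95)
})

test_that("noise-free CI validation returns zero estimates and references", {
  cfg <- tiny_cfg(snr = Inf, t2_grid = c(5, 15), reps = 6)
  r <- run_ci_validation(cfg)
  expect_true(all(r$mean_ci_est < 1e-6))
  expect_true(all(r$ci_reference < 1e-6))
  expect_true(all(r$contains_reference))
})

test_that("CI validation reports ordered ensemble limits", {
  cfg <- tiny_cfg(t2_grid = 10, reps = 40)
  r <- run_ci_validation(cfg)
  expect_true(r$ci_est_2_5 <= r$median_ci_est)
  expect_true(r$median_ci_est <= r$ci_est_97_5)
  expect_gt(r$mean_ci_est, 0)
})

test_that("subregion optimization skips infeasible partitions", {
  cfg <- tiny_cfg(t2_grid = 10, reps = 6)
  expect_warning(
    r <- run_subregion_optimization(roi_sizes = 3, fractions = 0.04,
                                    config = cfg),
    "infeasible")
  expect_null(r)
})

test_that("default grids span the simulated protocol ranges", {
  gc <- default_t2_grid(cardiac_protocol())
  gl <- default_t2_grid(liver)
  expect_equal(gc[1], 2.2)
  expect_equal(range(gl), c(1, 50))
  expect_true(all(diff(gc) <= 1) && all(diff(gl) == 1))
  expect_error(default_t2_grid(echo_protocol(c(1, 2), name = "custom")),
               "no default grid")
})
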