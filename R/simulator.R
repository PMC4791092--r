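#' Multi-coil noise model
#'
#' Per-channel Gaussian noise of a root-sum-of-squares (RSS) multi-coil
#' reconstruction: each of `n_coils` channels carries the same
#' monoexponential decay on its real and imaginary component plus
#' independent zero-mean Gaussian noise of SD `sigma`; channel magnitudes
#' are combined by RSS, so the magnitude noise follows a noncentral chi
#' distribution with `2 n_coils` degrees of freedom.
#'
#' @param n_coils Number of receive coils `L`, integer >= 1.
#' @param sigma Per-channel noise SD (intensity units), >= 0.
#' @return An object of class `coil_noise_model`.
#' @export
coil_noise_model <- function(n_coils, sigma) {
  if (n_coils < 1 || n_coils != round(n_coils))
    stop("n_coils must be a positive integer")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be non-negative")
  structure(list(n_coils = as.integer(n_coils), sigma = as.numeric(sigma)),
            class = "coil_noise_model")
}

#' Monte-Carlo experiment configuration
#'
#' Bundles everything one simulation experiment needs: the true T2* grid,
#' the SNR (defined as `s0 / sigma` with `s0` the per-channel decay
#' amplitude at TE = 0 and `sigma` the per-channel noise SD), the echo
#' protocol, coil counts, ROI size in pixels, the number of seeded
#' repetitions and the base seed.  `s0` is fixed at 100 intensity units by
#' default; all estimators are scale-invariant so the choice is
#' immaterial.
#'
#' @param t2_grid True T2* values in ms, all positive.
#' @param protocol An [echo_protocol].
#' @param snr Signal-to-noise ratio `s0 / sigma`, > 0.
#' @param n_coils Vector of coil counts to simulate.
#' @param roi_pixels Number of independent pixels averaged per ROI.
#' @param repetitions Repetitions per grid cell, >= 1.
#' @param seed Base RNG seed (integer).
#' @param s0 Noiseless RSS magnitude at TE = 0.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config(c(5, 20), liver_protocol(), repetitions = 100, seed = 1)
#' @export
simulation_config <- function(t2_grid, protocol, snr = 15,
                              n_coils = c(1, 6, 32), roi_pixels = 40,
                              repetitions = 2000, seed = 1, s0 = 100) {
  stopifnot(inherits(protocol, "echo_protocol"))
  if (any(t2_grid <= 0)) stop("t2_grid must be positive")
  if (snr <= 0) stop("snr must be positive")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (roi_pixels < 1) stop("roi_pixels must be >= 1")
  structure(list(t2_grid = as.numeric(t2_grid), protocol = protocol,
                 snr = as.numeric(snr), n_coils = as.integer(n_coils),
                 roi_pixels = as.integer(roi_pixels),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), s0 = as.numeric(s0)),
            class = "simulation_config")
}

#' Simulate magnitude decay signals
#'
#' `simulate_pixel()` draws one RSS-reconstructed magnitude decay: every
#' coil carries the identical monoexponential decay `s0 exp(-TE/T2*)` on
#' both its real and imaginary component, independent `N(0, sigma^2)`
#' noise is added per component, and coil magnitudes combine by root sum
#' of squares.  The noiseless RSS magnitude at TE = 0 is therefore
#' `sqrt(2 L) * s0`; the SNR `s0 / sigma` relates the per-channel decay
#' amplitude to the per-channel noise SD, which keeps the effective noise
#' floor (relative to the signal) comparable across coil counts.
#' `simulate_roi_pixels()` draws `roi_pixels` independent pixels and
#' `simulate_roi_signal()` returns their element-wise mean, emulating
#' ROI averaging before curve fitting.
#'
#' All three consume R's global RNG; call `set.seed()` beforehand for
#' reproducible draws.  The draw order is fixed (pixel-major; per coil,
#' per echo: real then imaginary), so the mean of `simulate_roi_pixels()`
#' under a given seed equals `simulate_roi_signal()` under the same seed.
#'
#' @param t2 True T2* in ms.
#' @param s0 Noiseless RSS magnitude at TE = 0.
#' @param noise A [coil_noise_model].
#' @param protocol An [echo_protocol].
#' @param roi_pixels Number of independent pixels.
#' @return `simulate_pixel()`: numeric magnitude vector (one per echo);
#'   `simulate_roi_pixels()`: a [roi_pixels()] object;
#'   `simulate_roi_signal()`: a [decay_signal].
#' @examples
#' set.seed(1)
#' simulate_pixel(10, 100, coil_noise_model(6, 100 / 15), liver_protocol())
#' @export
simulate_pixel <- function(t2, s0, noise, protocol) {
  stopifnot(inherits(noise, "coil_noise_model"),
            inherits(protocol, "echo_protocol"), t2 > 0, s0 >= 0)
  drop(cpp_simulate_pixels(protocol$tes, t2, s0, noise$sigma,
                           noise$n_coils, 1L))
}

#' @rdname simulate_pixel
#' @export
simulate_roi_pixels <- function(t2, s0, noise, protocol, roi_pixels = 40) {
  stopifnot(inherits(noise, "coil_noise_model"),
            inherits(protocol, "echo_protocol"), roi_pixels >= 1)
  m <- cpp_simulate_pixels(protocol$tes, t2, s0, noise$sigma,
                           noise$n_coils, as.integer(roi_pixels))
  roi_pixels(protocol, m)
}

#' @rdname simulate_pixel
#' @export
simulate_roi_signal <- function(t2, s0, noise, protocol, roi_pixels = 40) {
  roi <- simulate_roi_pixels(t2, s0, noise, protocol, roi_pixels)
  decay_signal(protocol, rowMeans(roi$pixel_signals))
}

# Deterministic per-cell seed stream: cells of one experiment get distinct,
# reproducible seeds derived from the base seed (kept inside 32-bit range).
derive_seed <- function(seed, cell) {
  as.integer((as.double(seed) + 48271 * as.double(cell)) %% 2147483647)
}
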