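#' Default simulated T2* grids
#'
#' One-millisecond grids over the simulated range of each clinical
#' protocol: true T2* values below the shortest echo time are not
#' simulated, giving 2.2-50 ms for the cardiac echo train (2.2 ms, then
#' 3-50 ms) and 1-50 ms for the liver echo train.
#'
#' @param protocol An [echo_protocol]; grids are defined for the two
#'   clinical protocols by name.
#' @return Numeric vector of true T2* values (ms).
#' @export
default_t2_grid <- function(protocol) {
  stopifnot(inherits(protocol, "echo_protocol"))
  switch(protocol$name,
         cardiac = c(2.2, seq(3, 50)),
         liver = seq(1, 50),
         stop("no default grid for protocol '", protocol$name,
              "'; supply t2_grid explicitly"))
}

# ROI statistics (echoes x repetitions) for one grid cell: `mean` is the
# pixel-mean magnitude fed to the magnitude-domain fits; `rms` is the root
# mean square over pixels, the unbiased carrier of the second moment
# (E[mean(M^2)] = S^2 + 2 L sigma^2 exactly) used by the true-sigma
# comparator.
simulate_cell_signals <- function(cfg, t2, n_coils) {
  y <- cpp_simulate_pixels(cfg$protocol$tes, t2, cfg$s0, cfg$s0 / cfg$snr,
                           n_coils, cfg$roi_pixels * cfg$repetitions)
  list(mean = cpp_group_means(y, cfg$roi_pixels),
       rms = sqrt(cpp_group_means(y * y, cfg$roi_pixels)))
}

percentile_span <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  q[2] - q[1]
}

# One estimator on a batch of ROI signal statistics; returns list(t2, ok).
estimate_batch <- function(estimator, te, signals, config, sigma, n_coils) {
  n_te <- nrow(signals$mean)
  r <- switch(estimator,
    adapts = cpp_adapts_batch(te, signals$mean, config$p1, config$p2),
    m2ncm_true_sigma = cpp_m2ncm_batch(te, signals$rms,
                                       2 * n_coils * sigma^2),
    truncation_only = cpp_adapts_batch(te, signals$mean, config$p1, 2),
    noise_corrected_only = cpp_adapts_batch(te, signals$mean, config$p1,
                                            n_te + 1),
    stop("unknown estimator: ", estimator))
  list(t2 = r[, "t2"], ok = r[, "converged"] == 1)
}

#' Accuracy and precision sweep
#'
#' Monte-Carlo characterisation of estimator bias and precision over a grid
#' of true T2* values and coil counts.  For every cell, `repetitions`
#' independent ROI-averaged signals are simulated and each requested
#' estimator is applied; the row reports the mean bias
#' `mean(estimate) - t2_true` and the 95% CI, i.e. the 2.5-97.5 percentile
#' span of the repetition ensemble.  Repetitions whose fit did not converge
#' are excluded and counted; a cell with more than 1% failures is flagged.
#'
#' Estimators: `"adapts"` (the model-switching estimator), `"m2ncm_true_sigma"`
#' (two-parameter second-moment comparator with the true noise term),
#' `"truncation_only"` and `"noise_corrected_only"` (the two component
#' models applied unconditionally).
#'
#' @param config A [simulation_config].
#' @param estimators Character vector of estimator names.
#' @param adapts An [adapts_config] used by the switching estimators.
#' @return A data frame with columns `t2_true`, `n_coils`, `estimator`,
#'   `mean_bias`, `ci95`, `repetitions`, `n_failed`, `flagged`.
#' @examples
#' cfg <- simulation_config(c(5, 20), liver_protocol(), n_coils = 6,
#'                          repetitions = 50, seed = 1)
#' run_accuracy_precision_sweep(cfg)
#' @export
run_accuracy_precision_sweep <- function(config,
                                         estimators = c("adapts",
                                                        "m2ncm_true_sigma"),
                                         adapts = adapts_config()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(adapts, "adapts_config"))
  sigma <- config$s0 / config$snr
  te <- config$protocol$tes
  grid <- expand.grid(t2_true = config$t2_grid, n_coils = config$n_coils)
  rows <- vector("list", nrow(grid) * length(estimators))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    t2 <- grid$t2_true[i]
    L <- grid$n_coils[i]
    set.seed(derive_seed(config$seed, i))
    signals <- simulate_cell_signals(config, t2, L)
    for (est in estimators) {
      r <- estimate_batch(est, te, signals, adapts, sigma, L)
      t2hat <- r$t2[r$ok]
      n_failed <- sum(!r$ok)
      k <- k + 1L
      rows[[k]] <- data.frame(
        t2_true = t2, n_coils = L, estimator = est,
        mean_bias = mean(t2hat) - t2,
        ci95 = percentile_span(t2hat),
        repetitions = length(t2hat), n_failed = n_failed,
        flagged = n_failed > 0.01 * config$repetitions)
    }
  }
  do.call(rbind, rows)
}

# Subregion CI estimates for every simulated ROI of one cell, sharing the
# code path of estimate_uncertainty(): chunked subregion means, batched
# fits, sqrt(n/N) correction, 3.92 * SD.  Returns list(t2_full, ci_est).
cell_ci_estimates <- function(cfg, t2, n_coils, fraction, adapts) {
  n_pix <- cfg$roi_pixels
  reps <- cfg$repetitions
  te <- cfg$protocol$tes
  y <- cpp_simulate_pixels(te, t2, cfg$s0, cfg$s0 / cfg$snr, n_coils,
                           n_pix * reps)
  full <- cpp_adapts_batch(te, cpp_group_means(y, n_pix),
                           adapts$p1, adapts$p2)

  n_sub <- max(2, round(fraction * n_pix))
  n_groups <- n_pix %/% n_sub
  if (n_groups < 2) stop("infeasible partition: fewer than two subregions")
  used <- n_groups * n_sub
  if (used < n_pix) {  # drop remainder pixels within each ROI block
    keep <- as.vector(outer(seq_len(used), (seq_len(reps) - 1L) * n_pix, "+"))
    y <- y[, keep, drop = FALSE]
  }
  sub <- cpp_adapts_batch(te, cpp_group_means(y, n_sub),
                          adapts$p1, adapts$p2)
  sub_t2 <- matrix(ifelse(sub[, "converged"] == 1, sub[, "t2"], NA_real_),
                   nrow = n_groups)
  raw_sd <- apply(sub_t2, 2, stats::sd, na.rm = TRUE)
  n_ok <- colSums(!is.na(sub_t2))
  ci_est <- 3.92 * sqrt(n_sub / n_pix) * raw_sd
  ci_est[n_ok < 3] <- NA_real_
  list(t2_full = full[full[, "converged"] == 1, "t2"], ci_est = ci_est)
}

#' Validation of the subregion CI estimate
#'
#' For each true T2*, simulates `repetitions` independent ROIs; every ROI
#' yields a subregion-based 95% CI estimate ([estimate_uncertainty()]
#' semantics), and the full-ROI estimates across repetitions yield the
#' reference CI (their 2.5-97.5 percentile span).  The row records the
#' distribution of the CI estimates against the reference, including
#' whether the reference lies within the 2.5-97.5% limits of the estimate
#' ensemble.
#'
#' @param config A [simulation_config] with a single coil count.
#' @param fraction Subregion fraction (default 4 %).
#' @param adapts An [adapts_config].
#' @return Data frame with columns `t2_true`, `mean_ci_est`,
#'   `median_ci_est`, `ci_est_2_5`, `ci_est_97_5`, `ci_reference`, `bias`
#'   (`mean_ci_est - ci_reference`), `contains_reference`, `repetitions`.
#' @export
run_ci_validation <- function(config, fraction = 0.04,
                              adapts = adapts_config()) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$n_coils) == 1)
  rows <- vector("list", length(config$t2_grid))
  for (i in seq_along(config$t2_grid)) {
    t2 <- config$t2_grid[i]
    set.seed(derive_seed(config$seed, i))
    cell <- cell_ci_estimates(config, t2, config$n_coils, fraction, adapts)
    ref <- percentile_span(cell$t2_full)
    ci <- cell$ci_est[!is.na(cell$ci_est)]
    q <- stats::quantile(ci, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[i]] <- data.frame(
      t2_true = t2, mean_ci_est = mean(ci), median_ci_est = q[2],
      ci_est_2_5 = q[1], ci_est_97_5 = q[3], ci_reference = ref,
      bias = mean(ci) - ref,
      contains_reference = ref >= q[1] && ref <= q[3],
      repetitions = length(ci))
  }
  do.call(rbind, rows)
}

#' Truncation-parameter sweep
#'
#' Bias and precision of the switching estimator over combinations of the
#' truncation multiple `p1` and minimum echo count `p2`, on a fixed
#' simulation configuration.  A single pair reduces to
#' [run_accuracy_precision_sweep()] with the `"adapts"` estimator.
#'
#' @param p1_values,p2_values Candidate parameter values.
#' @param config A [simulation_config].
#' @return Data frame with columns `p1`, `p2`, `t2_true`, `n_coils`,
#'   `mean_bias`, `ci95`, `repetitions`, `n_failed`, `flagged`.
#' @export
run_parameter_sweep <- function(p1_values, p2_values, config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list()
  for (p1 in p1_values) {
    for (p2 in p2_values) {
      r <- run_accuracy_precision_sweep(config, estimators = "adapts",
                                        adapts = adapts_config(p1, p2))
      r$estimator <- NULL
      out[[length(out) + 1L]] <- cbind(p1 = p1, p2 = p2, r)
    }
  }
  do.call(rbind, out)
}

#' Subregion-size optimisation for the CI estimate
#'
#' Bias and precision of the subregion CI estimator over combinations of
#' ROI size and subregion fraction.  Per cell the mean bias of the CI
#' estimate against the reference CI and the 2.5-97.5 percentile span of
#' the CI-estimate ensemble are reported.  Infeasible partitions (fewer
#' than two subregions) are skipped with a warning.
#'
#' @param roi_sizes ROI sizes in pixels.
#' @param fractions Subregion fractions.
#' @param config A [simulation_config] with a single coil count; its
#'   `roi_pixels` field is overridden by `roi_sizes`.
#' @param adapts An [adapts_config].
#' @return Data frame with columns `roi_size`, `fraction`, `t2_true`,
#'   `mean_bias`, `ci95_of_estimate`, `ci_reference`, `repetitions`.
#' @export
run_subregion_optimization <- function(roi_sizes, fractions, config,
                                       adapts = adapts_config()) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$n_coils) == 1)
  rows <- list()
  cell <- 0L
  for (n_pix in roi_sizes) {
    cfg <- config
    cfg$roi_pixels <- as.integer(n_pix)
    for (fraction in fractions) {
      n_sub <- max(2, round(fraction * n_pix))
      if (n_pix %/% n_sub < 2) {
        warning(sprintf("skipping infeasible partition: ROI %d, fraction %g",
                        n_pix, fraction))
        next
      }
      for (t2 in cfg$t2_grid) {
        cell <- cell + 1L
        set.seed(derive_seed(cfg$seed, cell))
        cc <- cell_ci_estimates(cfg, t2, cfg$n_coils, fraction, adapts)
        ref <- percentile_span(cc$t2_full)
        ci <- cc$ci_est[!is.na(cc$ci_est)]
        rows[[length(rows) + 1L]] <- data.frame(
          roi_size = n_pix, fraction = fraction, t2_true = t2,
          mean_bias = mean(ci) - ref,
          ci95_of_estimate = percentile_span(ci),
          ci_reference = ref, repetitions = length(ci))
      }
    }
  }
  do.call(rbind, rows)
}
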