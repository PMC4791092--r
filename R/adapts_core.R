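#' Estimator configuration
#'
#' The two tuning constants of the model-switching estimator: `p1`, the
#' truncation threshold expressed as a multiple of the initial T2* estimate
#' (echoes with `TE > p1 * t2_initial` are excluded), and `p2`, the minimum
#' number of retained echoes required to use the truncated two-parameter
#' fit.  The defaults (`p1 = 4.5`, `p2 = 9`) are the values selected by the
#' phantom and simulation optimisation of the method.
#'
#' @param p1 Truncation multiple, dimensionless, > 0.
#' @param p2 Minimum retained echo count, integer >= 2.
#' @return An object of class `adapts_config`.
#' @examples
#' adapts_config()
#' @export
adapts_config <- function(p1 = 4.5, p2 = 9) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (!is.finite(p1) || p1 <= 0) stop("p1 must be a positive number")
  if (!is.finite(p2) || p2 < 2 || p2 != round(p2))
    stop("p2 must be an integer >= 2")
  structure(list(p1 = p1, p2 = p2), class = "adapts_config")
}

#' @export
print.adapts_config <- function(x, ...) {
  cat(sprintf("<adapts_config> p1 = %g, p2 = %d\n", x$p1, as.integer(x$p2)))
  invisible(x)
}

#' Echo truncation relative to an initial T2* estimate
#'
#' Returns the indices of echoes retained for the truncated fit: those with
#' `TE <= p1 * t2_initial` (the boundary is inclusive; only echoes strictly
#' exceeding the threshold are excluded).  May return an empty vector for
#' very short `t2_initial`; the caller handles that case.
#'
#' @param protocol An [echo_protocol].
#' @param t2_initial Initial T2* estimate in ms, > 0.
#' @param config An [adapts_config].
#' @return Integer vector of retained echo indices (1-based, in order).
#' @examples
#' truncate_tes(cardiac_protocol(), t2_initial = 4, adapts_config())
#' @export
truncate_tes <- function(protocol, t2_initial, config = adapts_config()) {
  stopifnot(inherits(protocol, "echo_protocol"),
            inherits(config, "adapts_config"))
  if (!is.finite(t2_initial) || t2_initial <= 0)
    stop("t2_initial must be positive")
  which(protocol$tes <= config$p1 * t2_initial)
}

#' Adaptive model-switching T2* estimate
#'
#' The full estimator on one (typically ROI-averaged) magnitude series:
#'
#' 1. A three-parameter offset model (`PD exp(-TE/T2*) + C`) is fitted to
#'    all echoes, initialised by WLSL with the offset starting at the
#'    minimum measured value.  Its T2* is the initial estimate used only
#'    for truncation.
#' 2. Echoes with `TE > p1 * t2_initial` are excluded ([truncate_tes()]).
#' 3. If at least `p2` echoes remain, T2* is re-estimated by a
#'    two-parameter monoexponential fit on the retained echoes
#'    (`branch = "truncation"`).  Otherwise the series is deemed too short
#'    for a robust truncated fit and T2* comes from a three-parameter
#'    second-moment noise-corrected fit on all echoes
#'    (`branch = "noise_corrected"`).
#'
#' A pre-fit that stops at the iteration cap still carries its best
#' parameter vertex, which truncation uses as-is; a pre-fit at the T2*
#' clamp ceiling retains every echo because the threshold then exceeds all
#' TEs.  If truncation keeps fewer than `p2` echoes (including none), the
#' noise-corrected branch is taken.  The result is deterministic for
#' identical inputs.
#'
#' @param signal A [decay_signal] with at least four echoes (the pre-fit
#'   has three parameters) and at least one positive value.
#' @param config An [adapts_config].
#' @return An object of class `adapts_result`: list with `t2` (final
#'   estimate, ms), `branch`, `t2_initial`, `kept_te_indices` (echoes
#'   retained by truncation; the final fit uses exactly these on the
#'   truncation branch and all echoes on the noise-corrected branch),
#'   `params` (final fitted parameter set) and `diagnostics`.
#' @examples
#' p <- cardiac_protocol()
#' s <- decay_signal(p, 100 * exp(-p$tes / 10))
#' adapts_estimate(s)
#' @export
adapts_estimate <- function(signal, config = adapts_config()) {
  stopifnot(inherits(signal, "decay_signal"),
            inherits(config, "adapts_config"))
  y <- signal$values
  if (length(y) < 4)
    stop("at least four echoes are required (three-parameter pre-fit)")
  if (all(y == 0)) stop("signal is identically zero")
  r <- cpp_adapts(signal$protocol$tes, y, config$p1, config$p2)
  branch <- if (r$branch == 0) "truncation" else "noise_corrected"
  kept <- seq_len(r$n_kept)  # truncation keeps a prefix of the echo train
  params <- if (branch == "truncation") {
    monoexp_params(r$pd, r$t2)
  } else {
    noise_corrected_params(r$pd, r$t2, max(r$extra, 0))
  }
  structure(list(t2 = r$t2,
                 branch = branch,
                 t2_initial = r$t2_initial,
                 kept_te_indices = kept,
                 params = params,
                 config = config,
                 diagnostics = list(sse = r$sse,
                                    n_iterations = r$n_iterations,
                                    converged = r$converged,
                                    prefit_converged = r$prefit_converged)),
            class = "adapts_result")
}

#' @export
print.adapts_result <- function(x, ...) {
  cat(sprintf("<adapts_result> T2* = %.3f ms (%s branch)\n", x$t2, x$branch))
  cat(sprintf("  initial T2* (offset pre-fit): %.3f ms; echoes retained by truncation: %d\n",
              x$t2_initial, length(x$kept_te_indices)))
  invisible(x)
}
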