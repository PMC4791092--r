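#' Decay-model parameter sets
#'
#' Constructors for the three signal models used throughout the package:
#'
#' * `monoexp_params(pd, t2)` - two-parameter monoexponential decay
#'   `S(TE) = PD exp(-TE/T2*)`.
#' * `offset_params(pd, t2, c)` - monoexponential plus a constant offset
#'   `C >= 0` approximating the magnitude noise floor.
#' * `noise_corrected_params(pd, t2, k)` - second-moment noise-corrected
#'   model for root-sum-of-squares magnitudes: `E[M^2] = S^2 + k`, where for
#'   `L` coils with per-channel noise SD `sigma` the noise term equals
#'   `k = 2 L sigma^2` (fitted as one free parameter).
#'
#' @param pd Amplitude at TE = 0 (intensity units), > 0.
#' @param t2 Decay constant T2* in milliseconds, > 0.
#' @param c Constant offset (intensity units), >= 0.
#' @param k Noise term `2 L sigma^2` (squared-intensity units), >= 0.
#' @return A named list of class `t2_params` with a `model` attribute.
#' @examples
#' monoexp_params(100, 10)
#' offset_params(100, 10, 5)
#' @export
monoexp_params <- function(pd, t2) {
  new_params(list(pd = pd, t2 = t2), "monoexp")
}

#' @rdname monoexp_params
#' @export
offset_params <- function(pd, t2, c) {
  if (c < 0) stop("offset c must be non-negative")
  new_params(list(pd = pd, t2 = t2, c = c), "offset")
}

#' @rdname monoexp_params
#' @export
noise_corrected_params <- function(pd, t2, k) {
  if (k < 0) stop("noise term k must be non-negative")
  new_params(list(pd = pd, t2 = t2, k = k), "second_moment")
}

new_params <- function(x, model) {
  x <- lapply(x, as.numeric)
  if (anyNA(unlist(x)) || any(!is.finite(unlist(x))))
    stop("model parameters must be finite")
  if (x$pd <= 0) stop("pd must be strictly positive")
  if (x$t2 <= 0) stop("t2 must be strictly positive (milliseconds)")
  structure(x, class = "t2_params", model = model)
}

#' @export
print.t2_params <- function(x, ...) {
  cat(sprintf("<t2_params: %s> %s\n", attr(x, "model"),
              paste(sprintf("%s = %.6g", names(x), unlist(x)),
                    collapse = ", ")))
  invisible(x)
}

#' Forward evaluation of the decay models
#'
#' `predict_monoexp()` and `predict_offset()` return magnitudes
#' `PD exp(-TE/T2*) (+ C)`; `predict_second_moment()` returns expected
#' squared magnitudes `(PD exp(-TE/T2*))^2 + k`.
#'
#' @param params The matching parameter set (see [monoexp_params()]).
#' @param protocol An [echo_protocol].
#' @return Numeric vector, one value per echo time.
#' @examples
#' predict_monoexp(monoexp_params(100, 10), echo_protocol(c(5, 10)))
#' @export
predict_monoexp <- function(params, protocol) {
  stopifnot(attr(params, "model") == "monoexp")
  params$pd * exp(-protocol$tes / params$t2)
}

#' @rdname predict_monoexp
#' @export
predict_offset <- function(params, protocol) {
  stopifnot(attr(params, "model") == "offset")
  params$pd * exp(-protocol$tes / params$t2) + params$c
}

#' @rdname predict_monoexp
#' @export
predict_second_moment <- function(params, protocol) {
  stopifnot(attr(params, "model") == "second_moment")
  (params$pd * exp(-protocol$tes / params$t2))^2 + params$k
}

t2_ceiling <- function(protocol) 10 * max(protocol$tes)

#' Weighted least squares on the signal logarithm (WLSL)
#'
#' Closed-form initialiser for the exponential fits: weighted linear
#' regression of `log(S)` on TE with variance-stabilising weights `S^2`;
#' `pd = exp(intercept)`, `t2 = -1/slope`.  A non-decaying series (slope
#' >= 0) yields `t2` clamped to ten times the longest echo time, the same
#' ceiling enforced during nonlinear optimisation.
#'
#' @param signal A [decay_signal] with strictly positive values.
#' @return A `monoexp_params` object.
#' @examples
#' p <- cardiac_protocol()
#' s <- decay_signal(p, 100 * exp(-p$tes / 10))
#' wlsl_fit(s)
#' @export
wlsl_fit <- function(signal) {
  stopifnot(inherits(signal, "decay_signal"))
  if (any(signal$values <= 0))
    stop("WLSL requires strictly positive signal values (log-domain fit)")
  est <- cpp_wlsl(signal$protocol$tes, signal$values,
                  t2_ceiling(signal$protocol))
  monoexp_params(pd = est[1], t2 = est[2])
}

model_code <- c(monoexp = 0L, offset = 1L, second_moment = 2L)
n_free <- c(monoexp = 2L, offset = 3L, second_moment = 3L)

default_init <- function(model, signal) {
  w <- wlsl_fit(signal)
  switch(model,
    monoexp = w,
    offset = offset_params(w$pd, w$t2, min(signal$values)),
    second_moment = noise_corrected_params(w$pd, w$t2,
                                           min(signal$values)^2))
}

#' Least-squares fit of a decay model
#'
#' Minimises the sum of squared residuals between the model prediction and
#' the measured series with a derivative-free Nelder-Mead simplex (single
#' start, standard coefficients, relative tolerance 1e-8 on parameters and
#' SSE, at most 2000 iterations).  The `second_moment` model predicts the
#' measured magnitude by the square root of the noncentral-chi second
#' moment, `sqrt((PD exp(-TE/T2*))^2 + k)`, so residuals stay in the
#' magnitude domain for every model.  During optimisation `t2` is
#' constrained to `(0, 10 max(TE)]` and amplitude/offset/noise terms to
#' non-negative values via a penalty.
#'
#' @param model One of `"monoexp"`, `"offset"`, `"second_moment"`.
#' @param signal A [decay_signal].
#' @param init Optional starting parameter set of the matching class;
#'   defaults to the WLSL solution (offset initialised at the minimum
#'   measured value, noise term at the minimum squared value).
#' @return A list with `params` (fitted parameter set) and `diagnostics`
#'   (list with `sse`, `n_iterations`, `converged`).
#' @examples
#' p <- cardiac_protocol()
#' s <- decay_signal(p, 100 * exp(-p$tes / 10) + 8)
#' fit_model("offset", s)$params
#' @export
fit_model <- function(model = c("monoexp", "offset", "second_moment"),
                      signal, init = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(signal, "decay_signal"))
  if (length(signal$values) < n_free[[model]])
    stop(sprintf("under-determined fit: %d echoes for a %d-parameter model",
                 length(signal$values), n_free[[model]]))
  if (is.null(init)) init <- default_init(model, signal)
  stopifnot(inherits(init, "t2_params"))
  if (attr(init, "model") != model)
    stop("init parameter class does not match the requested model")
  r <- cpp_fit_model(model_code[[model]], signal$protocol$tes, signal$values,
                     unlist(init), t2_ceiling(signal$protocol))
  x <- r$params
  params <- switch(model,
    monoexp = monoexp_params(x[1], x[2]),
    offset = offset_params(x[1], x[2], max(x[3], 0)),
    second_moment = noise_corrected_params(x[1], x[2], max(x[3], 0)))
  list(params = params,
       diagnostics = list(sse = r$sse, n_iterations = r$n_iterations,
                          converged = r$converged))
}

#' Two-parameter second-moment fit with known noise level
#'
#' The near-optimal comparator used in the simulation studies: fits the
#' measured magnitudes to `sqrt(S^2 + 2 L sigma^2)` with the noise term
#' held fixed at its true value, leaving amplitude and T2* as the only
#' free parameters.  On a single-pixel series its residual bias is the gap
#' between `E[M]` and `sqrt(E[M^2])`, largest for a single coil; for ROI
#' data, feed the root mean square of the pixel magnitudes (per echo), for
#' which `E[mean(M^2)] = S^2 + 2 L sigma^2` holds exactly.
#'
#' @param signal A [decay_signal].
#' @param sigma True per-channel Gaussian noise SD (after any ROI averaging
#'   the term still refers to the single-pixel, per-channel SD).
#' @param n_coils Number of receive coils `L`.
#' @return As [fit_model()]: list with `params` (a `noise_corrected_params`
#'   with the fixed `k`) and `diagnostics`.
#' @export
m2ncm_fit <- function(signal, sigma, n_coils) {
  stopifnot(inherits(signal, "decay_signal"), sigma >= 0, n_coils >= 1)
  k <- 2 * n_coils * sigma^2
  w <- wlsl_fit(signal)
  r <- cpp_fit_model(3L, signal$protocol$tes, signal$values,
                     c(w$pd, w$t2), t2_ceiling(signal$protocol), k_fixed = k)
  list(params = noise_corrected_params(r$params[1], r$params[2], k),
       diagnostics = list(sse = r$sse, n_iterations = r$n_iterations,
                          converged = r$converged))
}
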