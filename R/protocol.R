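#' Echo-time protocol
#'
#' An ordered set of echo times (TE, milliseconds) of a multi-echo
#' gradient-echo acquisition; the independent variable of every decay fit.
#'
#' @param tes Numeric vector of echo times in milliseconds; strictly
#'   increasing, all positive, at least two.
#' @param name Free-text label, e.g. `"cardiac"` or `"liver"`.
#' @return An object of class `echo_protocol` (list with `tes`, `name`).
#' @examples
#' echo_protocol(c(2.5, 5, 7.5), name = "short")
#' @export
echo_protocol <- function(tes, name = "") {
  tes <- as.numeric(tes)
  if (length(tes) < 2) stop("an echo protocol needs at least two echo times")
  if (anyNA(tes) || any(!is.finite(tes))) stop("echo times must be finite")
  if (any(tes <= 0)) stop("echo times must be positive (milliseconds)")
  if (any(diff(tes) <= 0)) stop("echo times must be strictly increasing")
  structure(list(tes = tes, name = as.character(name)[1]),
            class = "echo_protocol")
}

#' Clinical multi-echo protocols
#'
#' Echo-time sets of the clinical multi-echo gradient-echo sequences used
#' for cardiac and liver iron-load imaging: 10 echoes spanning 2.5-25 ms
#' (cardiac, 2.5 ms spacing) and 1.3-20.1 ms (liver).
#'
#' @return An [echo_protocol].
#' @examples
#' cardiac_protocol()$tes
#' @export
cardiac_protocol <- function() {
  echo_protocol(c(2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 22.5, 25.0),
                name = "cardiac")
}

#' @rdname cardiac_protocol
#' @export
liver_protocol <- function() {
  echo_protocol(c(1.3, 3.4, 5.5, 7.6, 9.7, 11.8, 13.9, 16, 18, 20.1),
                name = "liver")
}

#' @export
print.echo_protocol <- function(x, ...) {
  cat(sprintf("<echo_protocol%s> %d echoes: %s ms\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              length(x$tes), paste(format(x$tes), collapse = ", ")))
  invisible(x)
}

#' Measured decay signal
#'
#' A magnitude decay series (single pixel or ROI average) paired with its
#' echo protocol.
#'
#' @param protocol An [echo_protocol].
#' @param values Non-negative magnitudes, one per echo (arbitrary intensity
#'   units).
#' @return An object of class `decay_signal` (list with `protocol`, `values`).
#' @export
decay_signal <- function(protocol, values) {
  stopifnot(inherits(protocol, "echo_protocol"))
  values <- as.numeric(values)
  if (length(values) != length(protocol$tes))
    stop("signal length must match the number of echo times")
  if (anyNA(values) || any(!is.finite(values)))
    stop("signal values must be finite")
  if (any(values < 0)) stop("magnitude values must be non-negative")
  structure(list(protocol = protocol, values = values),
            class = "decay_signal")
}

#' @export
print.decay_signal <- function(x, ...) {
  cat(sprintf("<decay_signal> %d echoes (%s)\n", length(x$values),
              if (nzchar(x$protocol$name)) x$protocol$name else "unnamed"))
  print(data.frame(te_ms = x$protocol$tes, value = x$values), row.names = FALSE)
  invisible(x)
}
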