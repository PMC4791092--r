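#' Multi-echo image stack
#'
#' One 2D slice acquired at several echo times: an array with dimensions
#' (rows, columns, echoes) plus the echo protocol.  Pixel spacing is
#' carried for information only and never affects fitting.
#'
#' @param images Numeric array `(nrow, ncol, n_echoes)` of non-negative
#'   magnitudes.
#' @param protocol An [echo_protocol] (one TE per echo plane).
#' @param pixel_spacing Optional numeric length-2 (mm), informational.
#' @param source Free-text tag of the originating format.
#' @return An object of class `multiecho_stack`.
#' @export
multiecho_stack <- function(images, protocol, pixel_spacing = NULL,
                            source = "array") {
  stopifnot(inherits(protocol, "echo_protocol"))
  images <- as.array(images)
  if (length(dim(images)) != 3)
    stop("images must be a (rows, cols, echoes) array")
  if (dim(images)[3] != length(protocol$tes))
    stop("number of echo planes must match the number of echo times")
  if (anyNA(images) || any(!is.finite(images)))
    stop("image values must be finite")
  if (any(images < 0)) stop("magnitude images must be non-negative")
  structure(list(images = images, protocol = protocol,
                 pixel_spacing = pixel_spacing, source = source),
            class = "multiecho_stack")
}

#' @export
print.multiecho_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<multiecho_stack> %d x %d pixels, %d echoes (%s; source: %s)\n",
              d[1], d[2], d[3],
              if (nzchar(x$protocol$name)) x$protocol$name else "unnamed",
              x$source))
  invisible(x)
}

#' Region-of-interest specification
#'
#' Either a logical/0-1 mask matching the in-plane image dimensions, or an
#' explicit list of pixel indices.  Indices are 1-based positions in
#' row-major (row-by-row) pixel order, the order in which subregion
#' partitioning later chunks the pixels.
#'
#' @param mask Logical or 0/1 matrix, same in-plane shape as the stack.
#' @param indices Integer vector of 1-based row-major pixel indices.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(mask = NULL, indices = NULL) {
  if (is.null(mask) == is.null(indices))
    stop("supply exactly one of mask or indices")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(mask %in% c(0, 1, TRUE, FALSE)))
      stop("mask must be binary")
    if (!any(mask == 1)) stop("ROI mask is empty")
    structure(list(mask = mask == 1, indices = NULL), class = "roi_spec")
  } else {
    indices <- as.integer(indices)
    if (length(indices) == 0) stop("ROI index list is empty")
    if (any(indices < 1)) stop("pixel indices are 1-based")
    if (anyDuplicated(indices)) stop("duplicate pixel indices")
    structure(list(mask = NULL, indices = indices), class = "roi_spec")
  }
}

# Row-major pixel indices of an roi_spec for a given stack.
roi_indices <- function(roi, stack) {
  d <- dim(stack$images)
  if (!is.null(roi$mask)) {
    if (!identical(dim(roi$mask), d[1:2]))
      stop("ROI mask dimensions do not match the image")
    # row-major order: walk rows, then columns
    idx <- which(t(roi$mask))
  } else {
    if (any(roi$indices > d[1] * d[2]))
      stop("ROI pixel index outside the image")
    idx <- sort(roi$indices)
  }
  idx
}

# Per-pixel signal matrix (echoes x pixels, row-major pixel order).
stack_roi_pixels <- function(stack, roi) {
  idx <- roi_indices(roi, stack)
  d <- dim(stack$images)
  row <- (idx - 1L) %/% d[2] + 1L
  col <- (idx - 1L) %% d[2] + 1L
  m <- vapply(seq_along(idx), function(i) stack$images[row[i], col[i], ],
              numeric(d[3]))
  roi_pixels(stack$protocol, m, pixel_ids = idx)
}

#' Read and write the tabular signal format
#'
#' A plain-text exchange format for per-pixel decay signals: CSV with a
#' header `te_ms,pixel_0,pixel_1,...`, one row per echo, period decimal
#' separator, UTF-8.  `write_signal_table()` and `read_signal_table()`
#' round-trip a [roi_pixels] object bit-exactly.
#'
#' @param path File path.
#' @param roi A [roi_pixels] object.
#' @param name Protocol label attached on reading.
#' @return `read_signal_table()`: a [roi_pixels] object.
#' @export
read_signal_table <- function(path, name = "") {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "te_ms")
    stop("first column of a signal table must be te_ms")
  if (ncol(d) < 2) stop("signal table holds no pixel columns")
  roi_pixels(echo_protocol(d$te_ms, name = name),
             as.matrix(d[, -1, drop = FALSE]))
}

#' @rdname read_signal_table
#' @export
write_signal_table <- function(roi, path) {
  stopifnot(inherits(roi, "roi_pixels"))
  m <- roi$pixel_signals
  d <- data.frame(te_ms = roi$protocol$tes, m, check.names = FALSE)
  names(d) <- c("te_ms", paste0("pixel_", seq_len(ncol(m)) - 1L))
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-echo NIfTI volume with a TE sidecar
#'
#' Expects a 3D volume whose third dimension indexes echoes, and a plain
#' text sidecar listing the echo times in milliseconds (whitespace-,
#' comma- or newline-separated).  Planes are sorted by TE.  A sidecar
#' whose values are all below 1 is rejected as likely being in seconds.
#'
#' @param volume_path Path to the NIfTI file.
#' @param te_path Path to the TE sidecar.
#' @return A [multiecho_stack].
#' @export
read_multiecho_nifti <- function(volume_path, te_path) {
  vol <- RNifti::readNifti(volume_path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3)
    stop("expected a 3D volume (x, y, echo)")
  tes <- scan(te_path, what = numeric(), sep = "", quiet = TRUE,
              comment.char = "#")
  if (length(tes) == 0) {
    tes <- scan(te_path, what = numeric(), sep = ",", quiet = TRUE)
  }
  if (length(tes) != dim(arr)[3])
    stop(sprintf("TE sidecar lists %d echo times but the volume has %d planes",
                 length(tes), dim(arr)[3]))
  if (all(tes < 1))
    stop("all sidecar TEs are below 1; they look like seconds - supply ms")
  ord <- order(tes)
  pixdim <- tryCatch(RNifti::pixdim(vol)[1:2], error = function(e) NULL)
  multiecho_stack(arr[, , ord, drop = FALSE],
                  echo_protocol(tes[ord]),
                  pixel_spacing = pixdim, source = "nifti")
}

#' Fit an ROI of a multi-echo stack
#'
#' ROI pipeline on image data: averages the ROI pixels per echo, runs
#' [adapts_estimate()] on the mean signal and, optionally,
#' [estimate_uncertainty()] on the per-pixel signals.  When the resulting
#' coefficient of variation exceeds `cov_threshold` an advisory flag is
#' raised suggesting the ROI delineation be reviewed.
#'
#' @param stack A [multiecho_stack].
#' @param roi A [roi_spec].
#' @param config An [adapts_config].
#' @param with_uncertainty Compute the subregion uncertainty estimate.
#' @param fraction Subregion fraction for the uncertainty estimate.
#' @param cov_threshold CoV above which the delineation-review advisory
#'   fires (default 0.30, within the range observed in patient ROIs).  The
#'   advisory also fires when the ROI estimate sits at its clamp ceiling
#'   (ten times the longest TE), the signature of an ROI with no visible
#'   decay.
#' @return A list of class `roi_report` with `t2`, `branch`, `fit`
#'   (the [adapts_estimate()] result), `n_pixels`, and, when requested,
#'   `uncertainty`, `ci95`, `cov` and `advisory`.
#' @export
fit_roi <- function(stack, roi, config = adapts_config(),
                    with_uncertainty = FALSE, fraction = 0.04,
                    cov_threshold = 0.30) {
  stopifnot(inherits(stack, "multiecho_stack"), inherits(roi, "roi_spec"))
  px <- stack_roi_pixels(stack, roi)
  fit <- adapts_estimate(decay_signal(stack$protocol,
                                      rowMeans(px$pixel_signals)), config)
  out <- list(t2 = fit$t2, branch = fit$branch, fit = fit,
              n_pixels = ncol(px$pixel_signals))
  if (with_uncertainty) {
    unc <- estimate_uncertainty(px, config, fraction)
    out$uncertainty <- unc
    out$ci95 <- unc$ci95_size
    out$cov <- unc$cov
    # a fit pinned at the T2* clamp ceiling (no decay visible, e.g. an
    # all-background ROI) is flagged regardless of its nominal CoV
    degenerate <- fit$t2 >= 0.99 * 10 * max(stack$protocol$tes)
    out$advisory <- unc$cov > cov_threshold || degenerate
  }
  class(out) <- "roi_report"
  out
}

#' @export
print.roi_report <- function(x, ...) {
  cat(sprintf("<roi_report> T2* = %.3f ms (%s branch, %d pixels)\n",
              x$t2, x$branch, x$n_pixels))
  if (!is.null(x$uncertainty)) {
    cat(sprintf("  95%% CI size = %.3f ms; CoV = %.3f%s\n", x$ci95, x$cov,
                if (isTRUE(x$advisory))
                  " - advisory: consider reviewing the ROI delineation"
                else ""))
  }
  invisible(x)
}
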