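# Minimal DICOM reader for single-frame magnitude images.
#
# Scope: Part-10 files, little-endian transfer syntaxes (explicit
# 1.2.840.10008.1.2.1 and implicit 1.2.840.10008.1.2), uncompressed
# single-frame pixel data, 8- or 16-bit.  Sequences are skipped.  This
# covers the plain multi-echo magnitude series the estimator consumes;
# compressed or enhanced multi-frame dialects are out of scope.

u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}

u32 <- function(bytes, pos) {
  lo <- u16(bytes, pos)
  hi <- u16(bytes, pos + 2L)
  hi * 65536 + lo
}

# VRs with a 2-byte reserved field and 4-byte length in explicit encoding.
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Walk one data element; returns list(tag, vr, value_raw, next_pos).
read_element <- function(bytes, pos, explicit) {
  group <- u16(bytes, pos)
  elem <- u16(bytes, pos + 2L)
  tag <- sprintf("%04X,%04X", group, elem)
  pos <- pos + 4L
  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (vr %in% LONG_VRS) {
      len <- u32(bytes, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- u16(bytes, pos + 2L)
      pos <- pos + 4L
    }
  } else {
    vr <- NA_character_
    len <- u32(bytes, pos)
    pos <- pos + 4L
  }
  if (len == 4294967295) {  # undefined length: scan for sequence delimiter
    p <- pos
    repeat {
      if (p + 7L > length(bytes))
        stop("unterminated undefined-length element at tag ", tag)
      if (u16(bytes, p) == 0xFFFE && u16(bytes, p + 2L) == 0xE0DD) {
        end <- p + 8L
        break
      }
      p <- p + 2L
    }
    list(tag = tag, vr = vr, value = raw(0), next_pos = end)
  } else {
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    list(tag = tag, vr = vr, value = value, next_pos = pos + len)
  }
}

dicom_string <- function(value) {
  # strip trailing space/null padding before decoding
  while (length(value) && value[length(value)] %in% as.raw(c(0L, 32L)))
    value <- value[-length(value)]
  rawToChar(value)
}

# Parse one file into the handful of attributes the reader needs.
parse_dicom <- function(path) {
  n <- file.size(path)
  bytes <- readBin(path, "raw", n)
  if (n < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L

  # File meta group (0002) is always explicit little-endian.
  transfer_syntax <- "1.2.840.10008.1.2.1"
  while (pos + 7L <= n && u16(bytes, pos) == 0x0002) {
    el <- read_element(bytes, pos, explicit = TRUE)
    if (el$tag == "0002,0010") transfer_syntax <- dicom_string(el$value)
    pos <- el$next_pos
  }
  explicit <- switch(transfer_syntax,
                     "1.2.840.10008.1.2.1" = TRUE,
                     "1.2.840.10008.1.2" = FALSE,
                     stop("unsupported transfer syntax ", transfer_syntax,
                          " in ", path))

  out <- list(file = path, echo_time = NA_real_, series_uid = NA_character_,
              image_type = NA_character_, rows = NA_integer_,
              cols = NA_integer_, bits = 16L, signed = FALSE,
              pixel_spacing = NULL, pixel_data = NULL,
              slope = 1, intercept = 0)
  while (pos + 7L <= n) {
    el <- read_element(bytes, pos, explicit)
    v <- el$value
    switch(el$tag,
      "0008,0008" = { out$image_type <- dicom_string(v) },
      "0018,0081" = { out$echo_time <- as.numeric(dicom_string(v)) },
      "0020,000E" = { out$series_uid <- dicom_string(v) },
      "0028,0010" = { out$rows <- u16(v, 1L) },
      "0028,0011" = { out$cols <- u16(v, 1L) },
      "0028,0030" = {
        out$pixel_spacing <- as.numeric(strsplit(dicom_string(v),
                                                 "\\\\")[[1]])
      },
      "0028,0100" = { out$bits <- u16(v, 1L) },
      "0028,0103" = { out$signed <- u16(v, 1L) == 1L },
      "0028,1052" = { out$intercept <- as.numeric(dicom_string(v)) },
      "0028,1053" = { out$slope <- as.numeric(dicom_string(v)) },
      "7FE0,0010" = { out$pixel_data <- v },
      NULL)
    pos <- el$next_pos
  }
  out
}

decode_pixels <- function(info) {
  if (is.null(info$pixel_data))
    stop("no pixel data in ", info$file)
  if (is.na(info$rows) || is.na(info$cols))
    stop("missing Rows/Columns in ", info$file)
  if (info$bits == 16) {
    vals <- readBin(info$pixel_data, "integer", n = info$rows * info$cols,
                    size = 2L, endian = "little", signed = info$signed)
    if (!info$signed) vals[vals < 0] <- vals[vals < 0] + 65536
  } else if (info$bits == 8) {
    vals <- as.integer(info$pixel_data[seq_len(info$rows * info$cols)])
  } else {
    stop("unsupported BitsAllocated ", info$bits, " in ", info$file)
  }
  # DICOM pixel data is stored row by row
  matrix(vals * info$slope + info$intercept,
         nrow = info$rows, ncol = info$cols, byrow = TRUE)
}

#' Read a multi-echo DICOM series
#'
#' Reads a directory of single-frame magnitude DICOM files belonging to
#' one multi-echo series, groups them by `EchoTime` and returns the planes
#' sorted by ascending TE (so file ordering is irrelevant).  Files missing
#' `EchoTime`, duplicate echo times and mixed `SeriesInstanceUID`s are
#' errors; images whose `ImageType` does not mark them as magnitude raise
#' a warning.  Only uncompressed little-endian single-frame files are
#' supported.
#'
#' @param directory Directory holding the series.
#' @return A [multiecho_stack].
#' @export
read_multiecho_dicom <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("need at least two DICOM files in ", directory)
  infos <- lapply(files, parse_dicom)

  missing_te <- vapply(infos, function(i) is.na(i$echo_time), logical(1))
  if (any(missing_te))
    stop("EchoTime missing in: ",
         paste(basename(files[missing_te]), collapse = ", "))
  uids <- unique(vapply(infos, `[[`, character(1), "series_uid"))
  uids <- uids[!is.na(uids)]
  if (length(uids) > 1)
    stop("directory mixes multiple series (SeriesInstanceUID values: ",
         paste(uids, collapse = ", "), ")")
  tes <- vapply(infos, `[[`, numeric(1), "echo_time")
  if (anyDuplicated(tes))
    stop("duplicate EchoTime values within the series: ",
         paste(tes[duplicated(tes)], collapse = ", "))

  types <- vapply(infos, `[[`, character(1), "image_type")
  is_mag <- vapply(strsplit(types, "\\\\"), function(tk)
    any(tk %in% c("M", "MAGNITUDE")), logical(1))
  if (any(!is.na(types) & !is_mag))
    warning("series contains images not marked as magnitude (ImageType)")

  ord <- order(tes)
  planes <- lapply(infos[ord], decode_pixels)
  d <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("echo planes have inconsistent dimensions")
  images <- array(unlist(planes), dim = c(d[1], d[2], length(planes)))
  multiecho_stack(images, echo_protocol(tes[ord]),
                  pixel_spacing = infos[[ord[1]]]$pixel_spacing,
                  source = "dicom")
}
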