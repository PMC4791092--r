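# Shared fixture builders.  Everything is generated in code at test time.

noiseless_signal <- function(protocol, pd = 100, t2 = 10, c = 0) {
  decay_signal(protocol, pd * exp(-protocol$tes / t2) + c)
}

# Homogeneous noiseless ROI: every pixel carries the same decay.
noiseless_roi <- function(protocol, n_pixels, pd = 100, t2 = 10) {
  v <- pd * exp(-protocol$tes / t2)
  roi_pixels(protocol, matrix(v, nrow = length(v), ncol = n_pixels))
}

sim_noise <- function(n_coils = 6, snr = 15, s0 = 100) {
  coil_noise_model(n_coils, s0 / snr)
}

# ---- minimal DICOM writer (explicit VR little endian) for reader tests ----

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

dcm_pad <- function(s) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
  v
}

# One data element, explicit VR little endian.
dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_u16(length(value_raw)), value_raw)
  }
}

# Write one single-frame 16-bit magnitude DICOM file.
write_test_dicom <- function(path, pixels, echo_time,
                             series_uid = "1.2.3.4", image_type = "ORIGINAL\\PRIMARY\\M",
                             with_echo_time = TRUE) {
  stopifnot(is.matrix(pixels))
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0010, "UI", dcm_pad("1.2.840.10008.1.2.1"))
  )
  px <- writeBin(as.integer(round(t(pixels))), raw(), size = 2,
                 endian = "little")  # row-major storage
  body <- c(
    dcm_element(0x0008, 0x0008, "CS", dcm_pad(image_type)),
    if (with_echo_time)
      dcm_element(0x0018, 0x0081, "DS", dcm_pad(format(echo_time))),
    dcm_element(0x0020, 0x000E, "UI", dcm_pad(series_uid)),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(nrow(pixels))),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(ncol(pixels))),
    dcm_element(0x0028, 0x0030, "DS", dcm_pad("2.0\\2.0")),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# A small multi-echo stack with known ground truth decay per pixel.
synthetic_stack <- function(protocol, nrow = 4, ncol = 5, pd = 1000,
                            t2 = 10) {
  n_te <- length(protocol$tes)
  img <- array(0, dim = c(nrow, ncol, n_te))
  for (e in seq_len(n_te))
    img[, , e] <- pd * exp(-protocol$tes[e] / t2)
  multiecho_stack(img, protocol)
}
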