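# Minimal synthetic DICOM slice writer (explicit VR little endian) used to
# build test series; independent of the package's reader.

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(if (vr %in% c("UI")) 0L else 0x20))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    head <- c(head, as.raw(c(0, 0)),
              writeBin(length(value_raw), raw(), size = 4, endian = "little"))
  } else {
    head <- c(head,
              writeBin(length(value_raw), raw(), size = 2, endian = "little"))
  }
  c(head, value_raw)
}

dcm_str <- function(s) charToRaw(s)
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")

write_test_dicom_slice <- function(path, pixels, position, series_uid,
                                   instance = 1L,
                                   orientation = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(0.7, 0.7),
                                   slope = 1, intercept = -1024) {
  rows <- ncol(pixels); cols <- nrow(pixels)  # pixels is (x, y)
  ts <- dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1"))
  meta_len <- dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(ts), raw(), size = 4,
                                   endian = "little"))
  px <- writeBin(as.integer(round(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_element(0x0020, 0x000E, "UI", dcm_str(series_uid)),
    dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_element(0x0020, 0x0032, "DS",
                dcm_str(paste(position, collapse = "\\"))),
    dcm_element(0x0020, 0x0037, "DS",
                dcm_str(paste(orientation, collapse = "\\"))),
    dcm_element(0x0028, 0x0010, "US", dcm_us(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_us(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_str(paste(pixel_spacing, collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_element(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    dcm_element(0x0028, 0x1053, "DS", dcm_str(as.character(slope))),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, ts, body), con)
  invisible(path)
}

# write a consistent synthetic series of n slices into dir; returns the
# stored pixel arrays (x, y, slice) for comparison
write_test_dicom_series <- function(dir, n_slices = 4L, rows = 6L,
                                    cols = 5L, spacing = c(0.7, 0.7, 0.625),
                                    slope = 1, intercept = -1024,
                                    uid = "1.2.826.0.1.999999.1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(1234)
  stored <- array(sample.int(3000L, cols * rows * n_slices, replace = TRUE),
                  dim = c(cols, rows, n_slices))
  # write in shuffled file order with descending instance numbers to prove
  # geometric sorting
  order_idx <- sample(n_slices)
  for (f in seq_len(n_slices)) {
    k <- order_idx[f]
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%02d.dcm", f)), stored[, , k],
      position = c(-10, 20, (k - 1) * spacing[3]), series_uid = uid,
      instance = n_slices - k + 1L,
      pixel_spacing = spacing[c(2, 1)], slope = slope,
      intercept = intercept)
  }
  stored
}
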