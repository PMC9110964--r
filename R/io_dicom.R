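# Minimal DICOM reader for uncompressed CT series.
#
# Scope: single-frame scalar CT slices, explicit or implicit VR little
# endian, native (unencapsulated) pixel data. This covers what the pipeline
# consumes; encapsulated transfer syntaxes, sequences of undefined length
# inside the main data set, and multi-frame enhanced CT are out of scope.

.dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one data set (sequence of tag/VR/length/value items) from raw bytes.
# Returns a named list tag -> raw value. Stops at PixelData (kept) or end.
.dcm_parse_dataset <- function(bytes, start, explicit_vr, wanted,
                               end = length(bytes)) {
  out <- list()
  pos <- start
  n <- end
  u16 <- function(p) readBin(bytes[p:(p + 1L)], "integer", size = 2L,
                             signed = FALSE, endian = "little")
  u32 <- function(p) readBin(bytes[p:(p + 3L)], "integer", size = 4L,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    tag <- .dcm_tag(group, element)
    pos <- pos + 4L
    if (explicit_vr) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% .dcm_long_vrs) {
        len <- u32(pos + 4L); pos <- pos + 8L
      } else {
        len <- u16(pos + 2L); pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- u32(pos); pos <- pos + 4L
    }
    if (len == -1L)  # 0xFFFFFFFF: undefined length
      stop(sprintf("format error: undefined-length element %s unsupported",
                   tag), call. = FALSE)
    if (len > 0 && pos + len - 1L > n)
      stop(sprintf("format error: element %s overruns file", tag),
           call. = FALSE)
    if (tag %in% wanted)
      out[[tag]] <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    if (tag == "7FE00010") break
  }
  out
}

.dcm_str <- function(x) if (is.null(x)) NULL else
  trimws(rawToChar(x[x != as.raw(0L)]))
.dcm_nums <- function(x) if (is.null(x)) NULL else
  as.numeric(strsplit(.dcm_str(x), "\\\\")[[1]])
.dcm_u16 <- function(x) readBin(x, "integer", size = 2L, signed = FALSE,
                                endian = "little")

.dcm_read_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 200L)
    stop(sprintf("format error: %s is not a DICOM file", basename(path)),
         call. = FALSE)
  explicit_vr <- TRUE
  start <- 1L
  if (length(bytes) > 132L &&
      rawToChar(bytes[129:132]) == "DICM") {
    # file meta group: always explicit VR little endian, prefixed by its
    # own group-length element (0002,0000) UL
    if (.dcm_tag(readBin(bytes[133:134], "integer", size = 2L,
                         signed = FALSE, endian = "little"),
                 readBin(bytes[135:136], "integer", size = 2L,
                         signed = FALSE, endian = "little")) != "00020000")
      stop(sprintf("format error: %s lacks meta group length",
                   basename(path)), call. = FALSE)
    grouplen <- readBin(bytes[141:144], "integer", size = 4L,
                        endian = "little")
    meta <- .dcm_parse_dataset(bytes, 145L, TRUE, wanted = "00020010",
                               end = 144L + grouplen)
    start <- 145L + grouplen
    ts <- .dcm_str(meta[["00020010"]])
    if (!is.null(ts)) {
      if (ts == "1.2.840.10008.1.2") explicit_vr <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop(sprintf("unsupported content: transfer syntax %s in %s",
                     ts, basename(path)), call. = FALSE)
    }
  }
  wanted <- c("00080060", "0020000E", "00200013", "00200032", "00200037",
              "00280010", "00280011", "00280030", "00280100", "00280103",
              "00281052", "00281053", "7FE00010")
  el <- .dcm_parse_dataset(bytes, start, explicit_vr, wanted)
  rows <- .dcm_u16(el[["00280010"]]); cols <- .dcm_u16(el[["00280011"]])
  bits <- .dcm_u16(el[["00280100"]])
  if (is.null(rows) || is.null(cols) || is.null(el[["7FE00010"]]))
    stop(sprintf("format error: %s lacks image pixel module",
                 basename(path)), call. = FALSE)
  if (bits != 16L)
    stop(sprintf("unsupported content: %d-bit pixel data in %s", bits,
                 basename(path)), call. = FALSE)
  signed <- !is.null(el[["00280103"]]) && .dcm_u16(el[["00280103"]]) == 1L
  px <- readBin(el[["7FE00010"]], "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  if (length(px) != rows * cols)
    stop(sprintf("format error: pixel data size mismatch in %s",
                 basename(path)), call. = FALSE)
  list(
    file = path,
    series_uid = .dcm_str(el[["0020000E"]]) %||% "",
    instance = as.integer(.dcm_str(el[["00200013"]]) %||% "0"),
    position = .dcm_nums(el[["00200032"]]) %||% c(0, 0, 0),
    orientation = .dcm_nums(el[["00200037"]]) %||% c(1, 0, 0, 0, 1, 0),
    pixel_spacing = .dcm_nums(el[["00280030"]]) %||% c(1, 1),
    slope = (.dcm_nums(el[["00281053"]]) %||% 1)[1],
    intercept = (.dcm_nums(el[["00281052"]]) %||% 0)[1],
    rows = rows, cols = cols,
    # DICOM raster order: column fastest within a row -> (x, y) matrix
    pixels = matrix(px, nrow = cols, ncol = rows)
  )
}

#' Read a CT DICOM series as a volume
#'
#' Reads every DICOM file in a directory, checks that they form a single
#' consistent series, sorts slices by Image Position (Patient) projected on
#' the slice normal (instance numbers are not trusted), applies the rescale
#' slope/intercept, and assembles a Hounsfield-unit
#' \code{\link{ct_volume}}.
#'
#' @param directory_path directory containing exactly one CT series.
#' @param phase acquisition phase tag for the volume.
#' @param spacing_tolerance maximum allowed relative deviation of
#'   slice-to-slice spacing from the median (default 1\%).
#' @return a \code{\link{ct_volume}} with \code{intensity_domain =
#'   "hounsfield"}.
#' @export
read_dicom_series <- function(directory_path, phase = c("native", "delayed"),
                              spacing_tolerance = 0.01) {
  phase <- match.arg(phase)
  if (!dir.exists(directory_path))
    stop(sprintf("I/O error: no such directory: %s", directory_path),
         call. = FALSE)
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("format error: directory contains no files", call. = FALSE)
  slices <- lapply(files, .dcm_read_slice)

  uids <- vapply(slices, `[[`, "", "series_uid")
  if (length(unique(uids)) != 1L)
    stop(sprintf(
      "format error: mixed series in directory (e.g. %s)",
      basename(slices[[which(uids != uids[1])[1]]]$file)), call. = FALSE)
  ref <- slices[[1]]
  for (s in slices) {
    if (s$rows != ref$rows || s$cols != ref$cols)
      stop(sprintf("format error: slice %s has mismatched matrix size",
                   basename(s$file)), call. = FALSE)
    if (max(abs(s$orientation - ref$orientation)) > 1e-4)
      stop(sprintf("geometry error: slice %s has a different orientation",
                   basename(s$file)), call. = FALSE)
    if (max(abs(s$pixel_spacing - ref$pixel_spacing)) > 1e-6)
      stop(sprintf("geometry error: slice %s has different pixel spacing",
                   basename(s$file)), call. = FALSE)
  }
  row_dir <- ref$orientation[1:3]   # direction of increasing column index
  col_dir <- ref$orientation[4:6]   # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$position * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(proj)
    zsp <- stats::median(gaps)
    if (zsp <= 0 || any(abs(gaps - zsp) > spacing_tolerance * zsp))
      stop("geometry error: non-uniform slice spacing beyond tolerance",
           call. = FALSE)
  } else zsp <- 1
  vox <- array(0, dim = c(ref$cols, ref$rows, nz))
  for (k in seq_len(nz))
    vox[, , k] <- slices[[k]]$pixels * slices[[k]]$slope +
      slices[[k]]$intercept
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  spacing <- c(ref$pixel_spacing[2], ref$pixel_spacing[1], zsp)
  direction <- cbind(row_dir, col_dir, normal)
  dimnames(direction) <- NULL
  ct_volume(vox, spacing = spacing, origin = slices[[1]]$position,
            direction = direction, phase = phase,
            intensity_domain = "hounsfield")
}
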