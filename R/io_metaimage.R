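# MetaImage (.mha / .mhd) reader and writer.
#
# The MetaImage format is a plain-text key = value header followed by (or
# referencing) a raw little/big-endian voxel block. DimSize order is
# (x, y, z) with x fastest, which matches this package's array layout, so
# voxels map 1:1 onto R array storage.

.met_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a MetaImage volume
#'
#' Reads a scalar 3D MetaImage (\code{.mha} with embedded data, or
#' \code{.mhd} header plus raw file) into a \code{\link{ct_volume}}. Voxel
#' values are taken verbatim; the result is tagged as Hounsfield-domain
#' unless the header carries the package's own \code{AnatomicalOrientation}
#' sidecar written by \code{\link{write_metaimage}} for shifted volumes.
#'
#' @param file_path path to a \code{.mha} or \code{.mhd} file.
#' @param phase acquisition phase to tag the volume with.
#' @return a \code{\link{ct_volume}}.
#' @export
read_metaimage <- function(file_path, phase = c("native", "delayed")) {
  phase <- match.arg(phase)
  if (!file.exists(file_path))
    stop(sprintf("I/O error: file not found: %s", file_path), call. = FALSE)
  bytes <- readBin(file_path, "raw", n = file.size(file_path))
  # header = text lines up to and including the ElementDataFile line
  nl <- which(bytes == as.raw(10L))
  hdr <- list()
  data_start <- NA_integer_
  prev <- 0L
  for (pos in nl) {
    line <- rawToChar(bytes[(prev + 1L):(pos - 1L)])
    line <- sub("\r$", "", line)
    prev <- pos
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                   line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("format error: bad header line: %s", line), call. = FALSE)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") { data_start <- pos + 1L; break }
  }
  if (is.na(data_start))
    stop("format error: header ended before ElementDataFile", call. = FALSE)
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop(sprintf("unsupported content: NDims = %d (only 3D scalar volumes)",
                 ndims), call. = FALSE)
  ncomp <- as.integer(hdr$ElementNumberOfChannels %||% "1")
  if (ncomp != 1L)
    stop("unsupported content: vector-valued image", call. = FALSE)
  if (isTRUE(tolower(hdr$CompressedData %||% "false") == "true"))
    stop("unsupported content: compressed MetaImage", call. = FALSE)
  dims <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  if (length(dims) != 3L || any(dims < 1L))
    stop("format error: bad DimSize", call. = FALSE)
  tp <- .met_types[[hdr$ElementType %||% ""]]
  if (is.null(tp))
    stop(sprintf("unsupported content: ElementType %s", hdr$ElementType),
         call. = FALSE)
  spacing <- as.numeric(strsplit(trimws(hdr$ElementSpacing %||%
                                          hdr$ElementSize %||% "1 1 1"),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$Offset %||% hdr$Position %||%
                                         "0 0 0"), "\\s+")[[1]])
  dirvals <- as.numeric(strsplit(trimws(hdr$TransformMatrix %||%
                                          "1 0 0 0 1 0 0 0 1"), "\\s+")[[1]])
  direction <- matrix(dirvals, 3, 3)  # rows of header = columns of axes
  msb <- tolower(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||%
                   "false") == "true"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    payload <- bytes[data_start:length(bytes)]
  } else {
    raw_path <- file.path(dirname(file_path), datafile)
    if (!file.exists(raw_path))
      stop(sprintf("I/O error: raw data file not found: %s", raw_path),
           call. = FALSE)
    payload <- readBin(raw_path, "raw", n = file.size(raw_path))
  }
  if (length(payload) < n * tp$size)
    stop("format error: voxel data truncated", call. = FALSE)
  vals <- readBin(payload, what = tp$what, n = n, size = tp$size,
                  signed = tp$signed, endian = if (msb) "big" else "little")
  domain <- if (identical(hdr$IntensityDomain, "shifted")) "shifted"
            else "hounsfield"
  ct_volume(array(as.double(vals), dim = dims), spacing = spacing,
            origin = origin, direction = direction, phase = phase,
            intensity_domain = domain)
}

#' Write a MetaImage volume
#'
#' Writes a \code{\link{ct_volume}} as an uncompressed MetaImage. A
#' \code{.mha} path embeds the voxel block in the same file; a \code{.mhd}
#' path writes a sidecar \code{.raw}. The band-shift domain tag is stored
#' in a private \code{IntensityDomain} header key so package round trips
#' are lossless; foreign readers ignore it.
#'
#' @param volume a \code{ct_volume}.
#' @param file_path output path ending in \code{.mha} or \code{.mhd}.
#' @param element_type MetaImage element type for on-disk storage.
#' @return the path, invisibly.
#' @export
write_metaimage <- function(volume, file_path,
                            element_type = c("MET_DOUBLE", "MET_FLOAT",
                                             "MET_SHORT", "MET_UCHAR")) {
  stopifnot(inherits(volume, "ct_volume"))
  element_type <- match.arg(element_type)
  .write_met(volume$voxels, volume_geometry(volume), file_path, element_type,
             extra = c(IntensityDomain = volume$intensity_domain))
  invisible(file_path)
}

.write_met <- function(arr, geom, file_path, element_type, extra = NULL) {
  ext <- tolower(tools::file_ext(file_path))
  if (!ext %in% c("mha", "mhd"))
    stop("I/O error: output path must end in .mha or .mhd", call. = FALSE)
  tp <- .met_types[[element_type]]
  local_data <- ext == "mha"
  raw_name <- paste0(tools::file_path_sans_ext(basename(file_path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(geom$direction), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(geom$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(geom$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(geom$dim, collapse = " ")),
    paste("ElementType =", element_type),
    if (length(extra)) paste(names(extra), "=", unname(extra)),
    paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name)
  )
  con <- tryCatch(file(file_path, "wb"),
                  error = function(e) stop(sprintf(
                    "I/O error: cannot open %s for writing", file_path),
                    call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  data_con <- con
  if (!local_data) {
    data_con <- file(file.path(dirname(file_path), raw_name), "wb")
    on.exit(close(data_con), add = TRUE)
  }
  vals <- as.vector(arr)
  if (tp$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, data_con, size = tp$size, endian = "little")
  invisible(file_path)
}

#' Write a binary mask as an 8-bit MetaImage
#'
#' Persists a \code{\link{binary_mask}} as a MET_UCHAR (0/1) MetaImage
#' volume with the mask's geometry.
#'
#' @param mask a \code{binary_mask}.
#' @param file_path output path (\code{.mha} or \code{.mhd}).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, file_path) {
  stopifnot(inherits(mask, "binary_mask"))
  .write_met(array(as.integer(mask$bits), dim = mask$geometry$dim),
             mask$geometry, file_path, "MET_UCHAR",
             extra = c(MaskLabel = mask$label))
  invisible(file_path)
}

#' Read a binary mask written by \code{write_mask}
#'
#' @param file_path path to the mask MetaImage.
#' @return a \code{\link{binary_mask}} (label restored if present).
#' @export
read_mask <- function(file_path) {
  vol <- read_metaimage(file_path)
  label <- "mask"
  first <- readLines(file_path, n = 30L, warn = FALSE)
  ml <- grep("^MaskLabel = ", first, value = TRUE)
  if (length(ml)) label <- sub("^MaskLabel = ", "", ml[1])
  binary_mask(array(vol$voxels != 0, dim = dim(vol$voxels)),
              volume_geometry(vol), label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
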