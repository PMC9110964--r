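#' Construct a CT volume
#'
#' The central container of the package: a 3D scalar grid together with its
#' physical geometry and an acquisition-phase tag. Voxel values are either
#' raw Hounsfield units (\code{intensity_domain = "hounsfield"}) or
#' continuous values on the 0-255 display scale after the linear band shift
#' (\code{intensity_domain = "shifted"}).
#'
#' Array dimension order is (x, y, z) = (column, row, slice); see
#' \link{renalseg-package} for the indexing convention.
#'
#' @param voxels numeric 3D array of voxel values.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel (0, 0, 0).
#' @param direction 3x3 orthonormal matrix; column j is the physical
#'   direction of index axis j.
#' @param phase \code{"native"} (non-contrast) or \code{"delayed"}
#'   (excretory phase).
#' @param intensity_domain \code{"hounsfield"} or \code{"shifted"}.
#' @return an object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3), phase = c("native", "delayed"),
                      intensity_domain = c("hounsfield", "shifted")) {
  phase <- match.arg(phase)
  intensity_domain <- match.arg(intensity_domain)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) || !is_orthonormal(direction))
    stop("`direction` must be a 3x3 orthonormal matrix", call. = FALSE)
  if (intensity_domain == "shifted") {
    rng <- range(voxels)
    if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
      stop("shifted-domain voxel values must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         direction = direction, phase = phase,
         intensity_domain = intensity_domain),
    class = "ct_volume")
}

is_orthonormal <- function(m, tol = 1e-6) {
  all(abs(crossprod(m) - diag(3)) < tol) && abs(abs(det(m)) - 1) < tol
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, phase=%s, domain=%s\n",
              d[1], d[2], d[3], x$phase, x$intensity_domain))
  cat(sprintf("  spacing (mm): %s | origin (mm): %s\n",
              paste(signif(x$spacing, 6), collapse = " x "),
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  intensity range: [%.2f, %.2f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Geometry of a volume or mask
#'
#' @param x a \code{ct_volume} or \code{binary_mask}.
#' @return list with \code{dim}, \code{spacing}, \code{origin},
#'   \code{direction}.
#' @export
volume_geometry <- function(x) {
  g <- if (inherits(x, "binary_mask")) x$geometry else
    list(dim = dim(x$voxels), spacing = x$spacing, origin = x$origin,
         direction = x$direction)
  g
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- volume_geometry(a); gb <- volume_geometry(b)
  all(ga$dim == gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol) &&
    all(abs(ga$direction - gb$direction) < tol)
}

#' Physical position of voxel centres
#'
#' Converts 0-based voxel indices to physical mm coordinates through
#' \code{origin + direction \%*\% (spacing * index)}.
#'
#' @param x a \code{ct_volume} or \code{binary_mask}.
#' @param index numeric matrix (n x 3) of 0-based indices, or length-3 vector.
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
voxel_to_physical <- function(x, index) {
  g <- volume_geometry(x)
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  t(g$origin + g$direction %*% (t(idx) * g$spacing))
}

#' Construct a binary mask
#'
#' A boolean grid sharing the geometry of the CT volume it was derived
#' from; the unit of all segmentation set-algebra.
#'
#' @param bits logical 3D array.
#' @param geometry geometry list (as \code{\link{volume_geometry}}) or the
#'   source \code{ct_volume}/\code{binary_mask} to copy geometry from.
#' @param label free-text provenance label (e.g. \code{"skeleton"},
#'   \code{"calculus"}, \code{"step3_dilated"}).
#' @return an object of class \code{binary_mask}.
#' @export
binary_mask <- function(bits, geometry, label = "mask") {
  if (!is.array(bits) || length(dim(bits)) != 3L)
    stop("`bits` must be a 3D array", call. = FALSE)
  storage.mode(bits) <- "logical"
  if (inherits(geometry, c("ct_volume", "binary_mask")))
    geometry <- volume_geometry(geometry)
  if (!all(dim(bits) == geometry$dim))
    stop("mask dimensions do not match geometry", call. = FALSE)
  structure(list(bits = bits, geometry = geometry, label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$bits)
  cat(sprintf("<binary_mask> '%s' %dx%dx%d, %d true voxels (%.2f%%)\n",
              x$label, d[1], d[2], d[3], sum(x$bits),
              100 * mean(x$bits)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a \code{binary_mask}.
#' @return integer count.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$bits)
}

stop_if_geometry_mismatch <- function(a, b, what = "masks") {
  if (!same_geometry(a, b))
    stop(sprintf("alignment error: %s have different geometry", what),
         call. = FALSE)
  invisible(TRUE)
}
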