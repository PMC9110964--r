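#' Band-shift specification
#'
#' The linear intensity transfer function that maps the diagnostic
#' Hounsfield band onto the 8-bit display range. Defaults implement
#' f(-548) = 0 and f(800) = 255; everything outside the band clamps to the
#' range ends.
#'
#' @param input_low,input_high Hounsfield band edges (must satisfy
#'   \code{input_low < input_high}).
#' @param output_low,output_high display-range edges.
#' @return a \code{band_shift_spec} object.
#' @export
band_shift_spec <- function(input_low = -548, input_high = 800,
                            output_low = 0, output_high = 255) {
  if (!(input_low < input_high) || !(output_low < output_high))
    stop("band edges must satisfy low < high", call. = FALSE)
  structure(list(input_low = input_low, input_high = input_high,
                 output_low = output_low, output_high = output_high),
            class = "band_shift_spec")
}

#' Apply the linear intensity band shift
#'
#' Maps voxel values with
#' \deqn{f(v) = out_{lo} + (v - in_{lo}) \frac{out_{hi} - out_{lo}}{in_{hi} - in_{lo}}}
#' clamping values outside \code{[input_low, input_high]} to the output
#' range ends. Output values are kept continuous (no 8-bit rounding), so
#' downstream thresholds compare against exact positions on the 0-255
#' scale.
#'
#' @param volume a Hounsfield-domain \code{\link{ct_volume}}.
#' @param spec a \code{\link{band_shift_spec}}.
#' @return a \code{ct_volume} with \code{intensity_domain = "shifted"}.
#' @export
band_shift <- function(volume, spec = band_shift_spec()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "band_shift_spec"))
  if (volume$intensity_domain != "hounsfield")
    stop("domain error: volume is already band-shifted", call. = FALSE)
  out <- volume
  out$voxels <- band_shift_values(volume$voxels, spec)
  out$intensity_domain <- "shifted"
  out
}

#' Band-shift scalar values
#'
#' The same linear map as \code{\link{band_shift}}, applied to bare
#' numbers; useful for expressing Hounsfield quantities on the display
#' scale (e.g. when auditing where a tissue lands relative to a threshold
#' band).
#'
#' @param v numeric vector or array of Hounsfield values.
#' @param spec a \code{\link{band_shift_spec}}.
#' @return numeric of the same shape on the display scale.
#' @export
band_shift_values <- function(v, spec = band_shift_spec()) {
  scale <- (spec$output_high - spec$output_low) /
    (spec$input_high - spec$input_low)
  pmin(pmax(spec$output_low + (v - spec$input_low) * scale,
            spec$output_low), spec$output_high)
}

#' Median denoising
#'
#' Replaces every voxel by the median of its cubic
#' \eqn{(2 \cdot radius + 1)^3} neighbourhood; borders are handled by
#' nearest-value replication. The default radius 1 (3x3x3 kernel) is the
#' smallest useful kernel and preserves thin infundibula.
#'
#' @param volume a \code{\link{ct_volume}} (either intensity domain).
#' @param radius neighbourhood radius in voxels (>= 1).
#' @return denoised \code{ct_volume} with unchanged geometry and domain.
#' @export
median_denoise <- function(volume, radius = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  out <- volume
  out$voxels <- cpp_median3d(volume$voxels, dim(volume$voxels), radius)
  out
}
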