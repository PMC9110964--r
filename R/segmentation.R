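#' Segmentation configuration
#'
#' Every threshold and structuring-element size of the fixed-band
#' segmentation, with the method's defaults. All thresholds live on the
#' shifted 0-255 display scale and are inclusive on both ends. The skeleton
#' (bone) is the tissue class whose band holds in both phases; the
#' contrast-filled collecting system enters the delayed band only; calculi
#' saturate the top of the native band.
#'
#' @param skeleton_native_lower,skeleton_native_upper native-phase bone
#'   band (defaults 117, 180).
#' @param skeleton_delayed_lower,skeleton_delayed_upper delayed-phase band
#'   (defaults 130, 255) containing bone plus contrast.
#' @param calculus_lower,calculus_upper native-phase stone band (defaults
#'   250, 255).
#' @param particle_cube_dim_skeleton cube structuring-element edge for
#'   skeleton-path particle removal (default 3).
#' @param particle_cube_dim_calculus cube edge for calculus particle
#'   removal (default 2).
#' @param dilation_cube_dim,dilation_iterations cube edge and iteration
#'   count for the dilation between the native and delayed paths.
#' @return a \code{segmentation_config} object.
#' @export
segmentation_config <- function(skeleton_native_lower = 117,
                                skeleton_native_upper = 180,
                                skeleton_delayed_lower = 130,
                                skeleton_delayed_upper = 255,
                                calculus_lower = 250,
                                calculus_upper = 255,
                                particle_cube_dim_skeleton = 3L,
                                particle_cube_dim_calculus = 2L,
                                dilation_cube_dim = 3L,
                                dilation_iterations = 1L) {
  cfg <- list(skeleton_native_lower = skeleton_native_lower,
              skeleton_native_upper = skeleton_native_upper,
              skeleton_delayed_lower = skeleton_delayed_lower,
              skeleton_delayed_upper = skeleton_delayed_upper,
              calculus_lower = calculus_lower,
              calculus_upper = calculus_upper,
              particle_cube_dim_skeleton = as.integer(particle_cube_dim_skeleton),
              particle_cube_dim_calculus = as.integer(particle_cube_dim_calculus),
              dilation_cube_dim = as.integer(dilation_cube_dim),
              dilation_iterations = as.integer(dilation_iterations))
  if (cfg$skeleton_native_lower >= cfg$skeleton_native_upper ||
      cfg$skeleton_delayed_lower >= cfg$skeleton_delayed_upper ||
      cfg$calculus_lower >= cfg$calculus_upper)
    stop("each lower threshold must be below its upper threshold",
         call. = FALSE)
  if (cfg$particle_cube_dim_skeleton < 1L ||
      cfg$particle_cube_dim_calculus < 1L || cfg$dilation_cube_dim < 1L ||
      cfg$dilation_iterations < 1L)
    stop("structuring-element dims and iterations must be >= 1",
         call. = FALSE)
  structure(cfg, class = "segmentation_config")
}

#' Whole-volume intensity histogram
#'
#' Equal-width histogram over the shifted 0-255 scale, used to audit where
#' tissue populations sit relative to the fixed threshold bands. Bins are
#' half-open \code{[edge_i, edge_{i+1})} with the last bin closed.
#'
#' @param volume a shifted-domain \code{\link{ct_volume}}.
#' @param n_bins number of bins (default 256).
#' @return an \code{intensity_histogram}: list with \code{bin_edges}
#'   (length \code{n_bins + 1}) and \code{counts}.
#' @export
compute_histogram <- function(volume, n_bins = 256L) {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$intensity_domain != "shifted")
    stop("histogram is defined on the shifted 0-255 scale", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("`n_bins` must be >= 1", call. = FALSE)
  edges <- seq(0, 255, length.out = n_bins + 1L)
  bin <- pmin(floor(as.vector(volume$voxels) / 255 * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts),
            class = "intensity_histogram")
}

#' Threshold a volume into a binary mask
#'
#' Bit is true iff \code{lower <= value <= upper} (both bounds inclusive).
#'
#' @param volume a shifted-domain \code{\link{ct_volume}}.
#' @param lower,upper inclusive band edges on the 0-255 scale.
#' @param label provenance label for the mask.
#' @return a \code{\link{binary_mask}}.
#' @export
binarize <- function(volume, lower, upper, label = "binarized") {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$intensity_domain != "shifted")
    stop("thresholds are defined on the shifted 0-255 scale", call. = FALSE)
  if (lower > upper)
    stop("argument error: lower > upper", call. = FALSE)
  binary_mask(volume$voxels >= lower & volume$voxels <= upper,
              volume_geometry(volume), label = label)
}

# cube structuring element offset windows: edge d spans offsets
# [-floor((d-1)/2), ceil((d-1)/2)]; the reflected element swaps the ends.
cube_offsets <- function(cube_dim) {
  a <- (cube_dim - 1L) %/% 2L
  b <- cube_dim - 1L - a
  list(lo = rep(-a, 3L), hi = rep(b, 3L),
       rlo = rep(-b, 3L), rhi = rep(a, 3L))
}

erode_bits <- function(bits, lo, hi)
  cpp_box_morph(bits, dim(bits), as.integer(lo), as.integer(hi), FALSE)
dilate_bits <- function(bits, lo, hi)
  cpp_box_morph(bits, dim(bits), as.integer(lo), as.integer(hi), TRUE)

#' Morphological particle removal
#'
#' Opening followed by closing with a solid cube structuring element of
#' edge \code{cube_dim} voxels, the small-object suppression used on every
#' thresholded mask. Opening is erosion followed by dilation with the
#' reflected element (and dually for closing), which keeps even-sized
#' elements translation-neutral. Out-of-grid voxels count as background for
#' erosion and dilation alike.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param cube_dim cube edge length in voxels (>= 1).
#' @return cleaned \code{binary_mask}.
#' @export
particle_removal <- function(mask, cube_dim = 3L) {
  stopifnot(inherits(mask, "binary_mask"))
  cube_dim <- as.integer(cube_dim)
  if (cube_dim < 1L) stop("`cube_dim` must be >= 1", call. = FALSE)
  o <- cube_offsets(cube_dim)
  b <- dilate_bits(erode_bits(mask$bits, o$lo, o$hi), o$rlo, o$rhi)  # open
  b <- erode_bits(dilate_bits(b, o$lo, o$hi), o$rlo, o$rhi)          # close
  binary_mask(b, mask$geometry,
              label = paste0(mask$label, "_cleaned"))
}

#' Morphological dilation
#'
#' Iterated dilation with a solid cube element of edge \code{cube_dim}.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param cube_dim cube edge length in voxels (>= 1).
#' @param iterations number of passes (>= 1).
#' @return dilated \code{binary_mask} (always a superset of the input).
#' @export
dilate <- function(mask, cube_dim = 3L, iterations = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  cube_dim <- as.integer(cube_dim); iterations <- as.integer(iterations)
  if (cube_dim < 1L || iterations < 1L)
    stop("`cube_dim` and `iterations` must be >= 1", call. = FALSE)
  o <- cube_offsets(cube_dim)
  b <- mask$bits
  for (i in seq_len(iterations)) b <- dilate_bits(b, o$lo, o$hi)
  binary_mask(b, mask$geometry, label = paste0(mask$label, "_dilated"))
}

#' Voxelwise mask intersection (logical AND)
#'
#' @param a,b \code{\link{binary_mask}}s with identical geometry.
#' @param label provenance label.
#' @return a \code{binary_mask}.
#' @export
intersect_masks <- function(a, b, label = "intersection") {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_geometry_mismatch(a, b)
  binary_mask(a$bits & b$bits, a$geometry, label = label)
}

#' Voxelwise mask subtraction (a AND NOT b)
#'
#' @param a,b \code{\link{binary_mask}}s with identical geometry.
#' @param label provenance label.
#' @return a \code{binary_mask}, always disjoint from \code{b}.
#' @export
subtract_masks <- function(a, b, label = "difference") {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_geometry_mismatch(a, b)
  binary_mask(a$bits & !b$bits, a$geometry, label = label)
}

#' Skeleton segmentation (six-step dual-phase thresholding)
#'
#' Extracts bone as the tissue class whose intensity band holds in both
#' phases:
#' \enumerate{
#'   \item binarize the native phase in the bone band (117-180);
#'   \item particle removal (open + close, cube edge 3);
#'   \item dilation (cube edge 3);
#'   \item binarize the delayed phase in the 130-255 band;
#'   \item particle removal on step 4 (cube edge 3);
#'   \item intersect step 3 with step 5 - the skeleton mask.
#' }
#' Both volumes must already live on the same grid (the delayed phase
#' resampled onto the native grid after co-registration).
#'
#' @param native_shifted,delayed_shifted_registered shifted-domain
#'   \code{\link{ct_volume}}s on a common grid.
#' @param config a \code{\link{segmentation_config}}.
#' @return list with \code{skeleton} (= step 6) and \code{intermediates}
#'   (named list \code{step1} ... \code{step6}).
#' @export
segment_skeleton <- function(native_shifted, delayed_shifted_registered,
                             config = segmentation_config()) {
  stop_if_geometry_mismatch(native_shifted, delayed_shifted_registered,
                            "native and delayed volumes")
  step1 <- binarize(native_shifted, config$skeleton_native_lower,
                    config$skeleton_native_upper, label = "step1_native_band")
  step2 <- particle_removal(step1, config$particle_cube_dim_skeleton)
  step2$label <- "step2_cleaned"
  step3 <- dilate(step2, config$dilation_cube_dim,
                  config$dilation_iterations)
  step3$label <- "step3_dilated"
  step4 <- binarize(delayed_shifted_registered,
                    config$skeleton_delayed_lower,
                    config$skeleton_delayed_upper,
                    label = "step4_delayed_band")
  step5 <- particle_removal(step4, config$particle_cube_dim_skeleton)
  step5$label <- "step5_cleaned"
  step6 <- intersect_masks(step3, step5, label = "skeleton")
  list(skeleton = step6,
       intermediates = list(step1 = step1, step2 = step2, step3 = step3,
                            step4 = step4, step5 = step5, step6 = step6))
}

#' Collecting-system extraction by subtraction
#'
#' The pelvicalyceal system is the delayed-band tissue that is not bone:
#' the cleaned delayed-band mask (step 5) minus the skeleton (step 6).
#' Because the delayed band (130-255) also contains stone intensities, a
#' stone sitting inside the collecting system is part of this mask; the
#' PSV convention in \code{\link{compute_metrics}} decides how that is
#' counted.
#'
#' @param step5 cleaned delayed-band \code{\link{binary_mask}}.
#' @param step6 skeleton \code{binary_mask}.
#' @return \code{binary_mask} disjoint from \code{step6}.
#' @export
segment_collecting_system <- function(step5, step6) {
  subtract_masks(step5, step6, label = "collecting_system")
}

#' Calculus (stone) segmentation
#'
#' Binarizes the native phase in the saturated stone band (250-255) and
#' removes sub-element particles with a cube of edge 2.
#'
#' @param native_shifted shifted-domain native \code{\link{ct_volume}}.
#' @param config a \code{\link{segmentation_config}}.
#' @return \code{binary_mask} labelled \code{"calculus"}.
#' @export
segment_calculus <- function(native_shifted,
                             config = segmentation_config()) {
  m <- binarize(native_shifted, config$calculus_lower,
                config$calculus_upper, label = "calculus_band")
  m <- particle_removal(m, config$particle_cube_dim_calculus)
  m$label <- "calculus"
  m
}

#' Run the full dual-phase segmentation pipeline
#'
#' Executes the complete chain on Hounsfield-domain inputs: band shift of
#' both phases, median denoising, rigid co-registration (native fixed,
#' delayed moving), resampling of the delayed phase onto the native grid,
#' then skeleton, collecting-system and calculus segmentation.
#'
#' @param native,delayed Hounsfield-domain \code{\link{ct_volume}}s.
#' @param config a \code{\link{segmentation_config}}.
#' @param shift a \code{\link{band_shift_spec}}.
#' @param median_radius median-filter radius in voxels.
#' @param register_settings optimizer settings
#'   (\code{\link{register_settings}}); set to \code{NULL} to skip
#'   registration (inputs already aligned).
#' @param verbose log each stage with voxel counts to the message stream.
#' @return a \code{segmentation_result}: list with \code{skeleton},
#'   \code{collecting_system}, \code{calculus}, \code{intermediates}
#'   (steps 1-6), \code{registration} (\code{registration_result} or
#'   \code{NULL}), \code{native_shifted}, \code{delayed_registered},
#'   \code{config}, \code{stage_log}.
#' @export
run_full_pipeline <- function(native, delayed,
                              config = segmentation_config(),
                              shift = band_shift_spec(),
                              median_radius = 1L,
                              register_settings = renalseg::register_settings(),
                              verbose = FALSE) {
  stopifnot(inherits(native, "ct_volume"), inherits(delayed, "ct_volume"))
  if (native$intensity_domain != "hounsfield" ||
      delayed$intensity_domain != "hounsfield")
    stop("run_full_pipeline expects Hounsfield-domain inputs", call. = FALSE)
  log <- list()
  note <- function(stage, detail) {
    log[[stage]] <<- detail
    if (verbose) message(sprintf("[%s] %s", stage, detail))
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  nat <- wrap("band_shift", band_shift(native, shift))
  del <- wrap("band_shift", band_shift(delayed, shift))
  note("band_shift", sprintf("band [%g, %g] -> [%g, %g]", shift$input_low,
                             shift$input_high, shift$output_low,
                             shift$output_high))
  nat <- wrap("median_denoise", median_denoise(nat, median_radius))
  del <- wrap("median_denoise", median_denoise(del, median_radius))
  note("median_denoise", sprintf("radius %d", as.integer(median_radius)))

  reg <- NULL
  if (!is.null(register_settings)) {
    reg <- wrap("coregister", coregister(nat, del, register_settings))
    del <- wrap("resample", resample(del, reg$transform, reference = nat))
    note("coregister", sprintf(
      "metric %.4f after %d iterations; trans (%.2f, %.2f, %.2f) mm",
      reg$final_metric, reg$iterations_run, reg$transform$translation[1],
      reg$transform$translation[2], reg$transform$translation[3]))
  } else {
    if (!same_geometry(nat, del))
      stop("stage 'coregister' failed: registration skipped but grids differ",
           call. = FALSE)
    note("coregister", "skipped (inputs assumed aligned)")
  }

  sk <- wrap("segment_skeleton", segment_skeleton(nat, del, config))
  note("segment_skeleton",
       sprintf("skeleton voxels: %d", mask_voxel_count(sk$skeleton)))
  cs <- wrap("segment_collecting_system",
             segment_collecting_system(sk$intermediates$step5, sk$skeleton))
  note("segment_collecting_system",
       sprintf("collecting-system voxels: %d", mask_voxel_count(cs)))
  ca <- wrap("segment_calculus", segment_calculus(nat, config))
  note("segment_calculus",
       sprintf("calculus voxels: %d", mask_voxel_count(ca)))

  structure(list(skeleton = sk$skeleton, collecting_system = cs,
                 calculus = ca, intermediates = sk$intermediates,
                 registration = reg, native_shifted = nat,
                 delayed_registered = del, config = config,
                 stage_log = log),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  cat(sprintf("  skeleton:          %d voxels\n",
              mask_voxel_count(x$skeleton)))
  cat(sprintf("  collecting system: %d voxels\n",
              mask_voxel_count(x$collecting_system)))
  cat(sprintf("  calculus:          %d voxels\n",
              mask_voxel_count(x$calculus)))
  invisible(x)
}
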