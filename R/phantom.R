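# Synthetic dual-phase CT phantom with analytic ground truth.
#
# The phantom is a stated world, not a tuning knob: tissue Hounsfield
# means are chosen once so that the default band shift places every tissue
# where the fixed segmentation bands expect it (the role the clinical
# scanner protocol plays for real data), and the geometry is a simple
# anatomical cartoon - a soft-tissue body, two vertical bone columns
# (spine/rib surrogates), a contrast-filled renal pelvis with calyx
# branches, and a stone inside the pelvis.

#' Phantom specification
#'
#' Defaults: 96^3 grid at 1 mm isotropic; tissue means background -80 HU,
#' soft tissue 40 HU, bone 300 HU, excreted contrast 450 HU (delayed phase
#' only), stone 900 HU; Gaussian noise SD 10 HU; the delayed phase is
#' misaligned by a 2 degree rotation about the slice axis plus a
#' (3, -2, 1) mm translation. Under the default band shift
#' f(h) = 255 (h + 548) / 1348 these means land at 88.5, 111.2, 160.4,
#' 188.8 and 255 (clamped), i.e. exactly where the fixed bands expect
#' them: bone inside [117, 180] and [130, 255], contrast inside [130, 255]
#' but above the native bone band, stone inside [250, 255], parenchyma
#' below 117.
#'
#' @param grid_shape voxel counts per axis.
#' @param spacing voxel size in mm.
#' @param hu named list of tissue means (\code{background},
#'   \code{soft_tissue}, \code{bone}, \code{contrast}, \code{stone}).
#' @param stone_ellipsoids list of \code{list(center=, semi_axes=)} in mm;
#'   must lie inside the collecting system.
#' @param pelvis \code{list(center=, semi_axes=)} of the renal-pelvis
#'   ellipsoid, mm.
#' @param calyces list of \code{list(direction=, radius=, length=)}
#'   cylindrical branches growing outward from the pelvis surface.
#' @param bone_cylinders list of \code{list(center_xy=, radius=)} vertical
#'   (z-axis) bone columns.
#' @param body \code{list(center_xy=, semi_axes_xy=)} elliptical-cylinder
#'   soft-tissue body.
#' @param misalignment \code{\link{rigid_transform}} applied when
#'   generating the delayed phase.
#' @param noise_sd Gaussian noise SD in HU.
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return a \code{phantom_spec}.
#' @export
phantom_spec <- function(
    grid_shape = c(96L, 96L, 96L),
    spacing = c(1, 1, 1),
    hu = list(background = -80, soft_tissue = 40, bone = 300,
              contrast = 450, stone = 900),
    stone_ellipsoids = list(list(center = c(48, 48, 48),
                                 semi_axes = c(8, 6, 5))),
    pelvis = list(center = c(48, 48, 48), semi_axes = c(16, 12, 10)),
    calyces = list(
      list(direction = c(0.894, 0.447, 0), radius = 4, length = 12),
      list(direction = c(0.894, -0.447, 0), radius = 4, length = 12),
      list(direction = c(-0.707, 0, 0.707), radius = 4, length = 12)),
    bone_cylinders = list(list(center_xy = c(16, 48), radius = 7),
                          list(center_xy = c(80, 48), radius = 7)),
    body = list(center_xy = c(48, 48), semi_axes_xy = c(40, 34)),
    misalignment = rigid_transform(rotation = c(0, 0, 2 * pi / 180),
                                   translation = c(3, -2, 1),
                                   center = c(47.5, 47.5, 47.5)),
    noise_sd = 10,
    seed = 42L) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         hu = hu, stone_ellipsoids = stone_ellipsoids, pelvis = pelvis,
         calyces = calyces, bone_cylinders = bone_cylinders, body = body,
         misalignment = misalignment, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
  spec
}

# normalize calyx directions and derive their start points on the pelvis
# surface: p0 = center + r(u) * u with r(u) the ellipsoid radius along u
calyx_segments <- function(spec) {
  ctr <- spec$pelvis$center; ax <- spec$pelvis$semi_axes
  lapply(spec$calyces, function(cy) {
    u <- cy$direction / sqrt(sum(cy$direction^2))
    r_ell <- 1 / sqrt(sum((u / ax)^2))
    list(p0 = ctr + r_ell * u, u = u, radius = cy$radius,
         length = cy$length)
  })
}

#' Audit phantom tissue bands against the segmentation thresholds
#'
#' For each tissue, computes the post-shift mean, the band(s) it is meant
#' to occupy, and the Gaussian probability mass its intensity distribution
#' places inside each threshold band (clamping at the display-range ends
#' taken into account). Fails a tissue when its shifted mean misses the
#' intended band.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param shift a \code{\link{band_shift_spec}}.
#' @param config a \code{\link{segmentation_config}}.
#' @return a \code{data.frame} report with one row per tissue/band check
#'   and an overall \code{"pass"} attribute.
#' @export
verify_bands <- function(spec, shift = band_shift_spec(),
                         config = segmentation_config()) {
  bands <- list(
    skeleton_native = c(config$skeleton_native_lower,
                        config$skeleton_native_upper),
    skeleton_delayed = c(config$skeleton_delayed_lower,
                         config$skeleton_delayed_upper),
    calculus = c(config$calculus_lower, config$calculus_upper))
  # tissue -> band it must occupy (TRUE) or avoid (FALSE)
  intent <- list(
    list(tissue = "bone", band = "skeleton_native", inside = TRUE),
    list(tissue = "bone", band = "skeleton_delayed", inside = TRUE),
    list(tissue = "contrast", band = "skeleton_delayed", inside = TRUE),
    list(tissue = "contrast", band = "skeleton_native", inside = FALSE),
    list(tissue = "stone", band = "calculus", inside = TRUE),
    list(tissue = "soft_tissue", band = "skeleton_native", inside = FALSE),
    list(tissue = "soft_tissue", band = "skeleton_delayed", inside = FALSE),
    list(tissue = "background", band = "skeleton_delayed", inside = FALSE))
  sd_hu <- spec$noise_sd
  rows <- lapply(intent, function(it) {
    mu <- spec$hu[[it$tissue]]
    band <- bands[[it$band]]
    f_mu <- band_shift_values(mu, shift)
    inside <- f_mu >= band[1] && f_mu <= band[2]
    # probability mass of N(mu, sd) landing inside the band after the
    # clamped linear map, computed in HU space
    scale <- (shift$output_high - shift$output_low) /
      (shift$input_high - shift$input_low)
    lo_hu <- shift$input_low + (band[1] - shift$output_low) / scale
    hi_hu <- shift$input_low + (band[2] - shift$output_low) / scale
    lo_eff <- if (band[1] <= shift$output_low) -Inf else lo_hu
    hi_eff <- if (band[2] >= shift$output_high) Inf else hi_hu
    mass <- if (sd_hu > 0)
      stats::pnorm(hi_eff, mu, sd_hu) - stats::pnorm(lo_eff, mu, sd_hu)
    else as.numeric(mu >= lo_eff && mu <= hi_eff)
    data.frame(tissue = it$tissue, band = it$band, hu_mean = mu,
               shifted_mean = f_mu, intended_inside = it$inside,
               mean_inside = inside, band_mass = mass,
               pass = inside == it$inside)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Generate a dual-phase phantom with ground truth
#'
#' Builds the native phase as per-label Hounsfield means plus seeded
#' Gaussian noise; the delayed phase shares the anatomy with the
#' collecting-system region raised to the contrast mean (stone and bone
#' unchanged), drawn with its own noise, and is then resampled through the
#' specified rigid misalignment (so interpolation smoothing is realistic).
#' The stone is present in both phases. Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{native} and \code{delayed}
#'   (\code{\link{ct_volume}}s, Hounsfield domain) and \code{truth}, a
#'   \code{phantom_ground_truth}: \code{label_map} (integer array, legend
#'   in \code{labels}), analytic \code{stone_mm3} and
#'   \code{collecting_system_mm3}, and the true \code{misalignment} (the
#'   transform a registration of native onto delayed should invert).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  audit <- verify_bands(spec)
  if (!attr(audit, "pass")) {
    bad <- audit[!audit$pass, ]
    stop(sprintf(
      "spec error: tissue/band placement failed: %s",
      paste(sprintf("%s vs %s", bad$tissue, bad$band), collapse = ", ")),
      call. = FALSE)
  }
  d <- spec$grid_shape; sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  lab <- array(0L, dim = d)  # 0 background
  bd <- spec$body
  body_in <- ((X - bd$center_xy[1]) / bd$semi_axes_xy[1])^2 +
    ((Y - bd$center_xy[2]) / bd$semi_axes_xy[2])^2 <= 1
  lab[body_in] <- 1L  # soft tissue / parenchyma
  for (bc in spec$bone_cylinders) {
    inb <- (X - bc$center_xy[1])^2 + (Y - bc$center_xy[2])^2 <=
      bc$radius^2
    lab[inb] <- 2L
  }
  pv <- spec$pelvis
  cs_in <- ((X - pv$center[1]) / pv$semi_axes[1])^2 +
    ((Y - pv$center[2]) / pv$semi_axes[2])^2 +
    ((Z - pv$center[3]) / pv$semi_axes[3])^2 <= 1
  for (seg in calyx_segments(spec)) {
    wx <- X - seg$p0[1]; wy <- Y - seg$p0[2]; wz <- Z - seg$p0[3]
    s <- wx * seg$u[1] + wy * seg$u[2] + wz * seg$u[3]
    perp2 <- wx^2 + wy^2 + wz^2 - s^2
    cs_in <- cs_in | (s >= 0 & s <= seg$length & perp2 <= seg$radius^2)
  }
  lab[cs_in] <- 3L  # collecting system
  stone_vol <- 0
  for (st in spec$stone_ellipsoids) {
    sin_ <- ((X - st$center[1]) / st$semi_axes[1])^2 +
      ((Y - st$center[2]) / st$semi_axes[2])^2 +
      ((Z - st$center[3]) / st$semi_axes[3])^2 <= 1
    if (any(sin_ & !cs_in))
      stop("spec error: stone ellipsoid not contained in the collecting system",
           call. = FALSE)
    lab[sin_] <- 4L
    stone_vol <- stone_vol + 4 / 3 * pi * prod(st$semi_axes)
  }

  mu_native <- c(spec$hu$background, spec$hu$soft_tissue, spec$hu$bone,
                 spec$hu$soft_tissue, spec$hu$stone)[lab + 1L]
  mu_delayed <- c(spec$hu$background, spec$hu$soft_tissue, spec$hu$bone,
                  spec$hu$contrast, spec$hu$stone)[lab + 1L]

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  n <- prod(d)
  noise1 <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  noise2 <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  noise3 <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0

  native <- ct_volume(array(mu_native + noise1, dim = d), spacing = sp,
                      phase = "native")
  delayed_aligned <- ct_volume(array(mu_delayed + noise2, dim = d),
                               spacing = sp, phase = "delayed")
  delayed <- resample(delayed_aligned, spec$misalignment,
                      reference = delayed_aligned,
                      default_value = spec$hu$background)
  # out-of-field voxels get background mean plus their own noise draw: a
  # real reconstruction is noisy everywhere, and a constant fill would put
  # an artificial sharp column into any joint intensity histogram
  if (spec$noise_sd > 0) {
    support <- ct_volume(array(1, dim = d), spacing = sp, phase = "delayed")
    inside <- resample(support, spec$misalignment, reference = support,
                       default_value = 0)$voxels > 0.999
    delayed$voxels[!inside] <- spec$hu$background + noise3[!inside]
  }

  # analytic collecting-system cavity volume (stone included): pelvis
  # ellipsoid plus calyx cylinders; the cylinders start on the pelvis
  # surface, so the overlap neglected here is a thin cap per branch
  cs_vol <- 4 / 3 * pi * prod(pv$semi_axes) +
    sum(vapply(spec$calyces, function(cy) pi * cy$radius^2 * cy$length, 0))

  truth <- structure(list(
    label_map = lab,
    labels = c("background" = 0L, "soft_tissue" = 1L, "bone" = 2L,
               "collecting_system" = 3L, "stone" = 4L),
    stone_mm3 = stone_vol,
    collecting_system_mm3 = cs_vol,
    misalignment = spec$misalignment,
    spec = spec), class = "phantom_ground_truth")
  list(native = native, delayed = delayed, truth = truth)
}

#' Ground-truth mask for a phantom label
#'
#' @param truth a \code{phantom_ground_truth}.
#' @param label one of \code{"background"}, \code{"soft_tissue"},
#'   \code{"bone"}, \code{"collecting_system"}, \code{"stone"}, or a
#'   vector of these (union).
#' @param geometry geometry to stamp on the mask (defaults to unit spacing
#'   native grid of the truth's spec).
#' @return a \code{\link{binary_mask}}.
#' @export
truth_mask <- function(truth, label, geometry = NULL) {
  stopifnot(inherits(truth, "phantom_ground_truth"))
  ids <- truth$labels[label]
  if (anyNA(ids)) stop("unknown phantom label", call. = FALSE)
  if (is.null(geometry))
    geometry <- list(dim = dim(truth$label_map),
                     spacing = truth$spec$spacing,
                     origin = c(0, 0, 0), direction = diag(3))
  binary_mask(array(truth$label_map %in% ids, dim = dim(truth$label_map)),
              geometry, label = paste(label, collapse = "+"))
}

#' Dice overlap of two masks
#'
#' @param a,b \code{\link{binary_mask}}s on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  inter <- sum(a$bits & b$bits)
  denom <- sum(a$bits) + sum(b$bits)
  if (denom == 0) return(NA_real_)
  2 * inter / denom
}
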