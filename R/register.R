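#' Resample a volume through a rigid transform
#'
#' Resamples \code{moving} onto the grid of \code{reference} with trilinear
#' interpolation: the output voxel at physical point p takes the moving
#' volume's value at \code{transform(p)}. Points falling outside the moving
#' grid are filled with \code{default_value} (by default the Hounsfield
#' band floor, or 0 for shifted-domain volumes).
#'
#' @param moving \code{\link{ct_volume}} to resample.
#' @param transform a \code{\link{rigid_transform}} mapping reference-space
#'   points into moving space.
#' @param reference \code{ct_volume} providing the output grid.
#' @param default_value fill value for out-of-field voxels.
#' @return a \code{ct_volume} on the reference grid (phase and domain
#'   copied from \code{moving}).
#' @export
resample <- function(moving, transform = rigid_transform(),
                     reference = moving, default_value = NULL) {
  stopifnot(inherits(moving, "ct_volume"),
            inherits(transform, "rigid_transform"),
            inherits(reference, "ct_volume"))
  if (is.null(default_value))
    default_value <- if (moving$intensity_domain == "shifted") 0 else -548
  gm <- volume_geometry(moving); gr <- volume_geometry(reference)
  vox <- cpp_resample_rigid(
    moving$voxels, gm$dim, gm$spacing, gm$origin, t(gm$direction),
    gr$dim, gr$spacing, gr$origin, gr$direction,
    rotation_matrix(transform$rotation), transform$translation,
    transform$center, default_value)
  out <- reference
  out$voxels <- vox
  out$phase <- moving$phase
  out$intensity_domain <- moving$intensity_domain
  out
}

#' Registration optimizer settings
#'
#' Defaults follow a desk-scale, deterministic setup: Mattes-style mutual
#' information from a 32x32 joint histogram over a fixed random sample of
#' fixed-volume voxels, regular-step gradient descent (step halving on
#' direction reversal), two resolution levels, and a recorded sampling
#' seed.
#'
#' @param max_iterations gradient-descent iteration cap per level.
#' @param n_samples fixed-image samples used for the metric.
#' @param n_bins joint-histogram bins per intensity axis.
#' @param initial_step,min_step step lengths in scaled parameter units
#'   (about 1 mm per unit).
#' @param rotation_scale mm of peripheral motion per radian used to make
#'   rotation steps commensurate with translation steps.
#' @param n_levels resolution levels (level L uses a 2^(L-1) subsampled
#'   grid).
#' @param sample_margin_mm samples closer than this to a volume face are
#'   excluded, so the effective overlap stays constant while the optimiser
#'   moves (guards against the mutual-information overlap-shrink bias).
#' @param sampling_seed RNG seed for drawing metric samples.
#' @return a list of settings.
#' @export
register_settings <- function(max_iterations = 100L, n_samples = 20000L,
                              n_bins = 32L, initial_step = 2.0,
                              min_step = 0.005, rotation_scale = 50,
                              n_levels = 2L, sample_margin_mm = 8,
                              sampling_seed = 20260909L) {
  list(max_iterations = as.integer(max_iterations),
       n_samples = as.integer(n_samples), n_bins = as.integer(n_bins),
       initial_step = initial_step, min_step = min_step,
       rotation_scale = rotation_scale, n_levels = as.integer(n_levels),
       sample_margin_mm = sample_margin_mm,
       sampling_seed = as.integer(sampling_seed))
}

# intensity-weighted centre of mass in physical coordinates (weights
# shifted to start at zero so the darkest tissue carries no weight)
intensity_centroid <- function(volume) {
  v <- as.vector(volume$voxels)
  w <- v - min(v)
  d <- dim(volume$voxels)
  idx <- cbind(rep_len(seq_len(d[1]) - 1L, length(v)),
               rep_len(rep(seq_len(d[2]) - 1L, each = d[1]), length(v)),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  p <- voxel_to_physical(volume, idx)
  colSums(p * w) / sum(w)
}

# Gaussian-pyramid level: smooth with sigma = factor voxels (renormalized
# borders), then stride-subsample (voxel centres retained, spacing scaled).
# Smoothing before decimation is essential: without it, voxel noise puts
# sharp spurious optima into the mutual-information landscape.
pyramid_level <- function(volume, factor, sigma = factor) {
  out <- volume
  if (sigma > 0)
    out$voxels <- cpp_gauss3d(out$voxels, dim(out$voxels), sigma, TRUE)
  if (factor > 1L) {
    d <- dim(out$voxels)
    out$voxels <- out$voxels[seq(1L, d[1], by = factor),
                             seq(1L, d[2], by = factor),
                             seq(1L, d[3], by = factor), drop = FALSE]
    out$spacing <- out$spacing * factor
  }
  out
}

#' Rigid co-registration by Mattes mutual information
#'
#' Estimates the rigid transform mapping points of the fixed volume's
#' space onto the moving volume such that resampling the moving volume
#' through it maximises mutual information with the fixed volume. The
#' metric follows the Mattes formulation: a joint intensity histogram over
#' a fixed random subset of fixed-image voxels, with linear partial-volume
#' weighting in both intensity axes and trilinear interpolation of the
#' moving image; the optimiser is a regular-step gradient descent on scaled
#' parameters with step halving whenever the descent direction reverses.
#' The reported \code{final_metric} uses the negated-similarity convention
#' (more negative = better aligned).
#'
#' Deterministic for a fixed \code{sampling_seed}: the sample set is drawn
#' once per resolution level, so the objective is a fixed smooth function
#' of the six parameters.
#'
#' @param fixed,moving \code{\link{ct_volume}}s sharing an intensity
#'   domain and overlapping physically.
#' @param settings see \code{\link{register_settings}}.
#' @param initial_transform optional starting \code{\link{rigid_transform}}.
#' @return a \code{registration_result}: list with \code{transform},
#'   \code{final_metric}, \code{iterations_run}, \code{converged},
#'   \code{sampling_seed}.
#' @export
coregister <- function(fixed, moving, settings = register_settings(),
                       initial_transform = NULL) {
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"))
  if (fixed$intensity_domain != moving$intensity_domain)
    stop("fixed and moving volumes must share an intensity domain",
         call. = FALSE)
  gf <- volume_geometry(fixed)
  center <- as.numeric(voxel_to_physical(fixed, (gf$dim - 1) / 2))
  if (is.null(initial_transform)) {
    # moments initialisation: start the translation at the offset between
    # the intensity centroids of the two volumes (the standard companion
    # of gradient-descent registration; a cold identity start can sit on
    # a noise-induced ridge of the metric)
    t0 <- intensity_centroid(moving) - intensity_centroid(fixed)
    x0 <- c(0, 0, 0, t0)
  } else {
    x0 <- c(initial_transform$rotation * settings$rotation_scale,
            initial_transform$translation)
  }

  # zero-overlap guard: moving corners vs fixed corners bounding boxes
  corner_idx <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  fc <- voxel_to_physical(fixed, corner_idx %*% diag(gf$dim - 1))
  gm <- volume_geometry(moving)
  mc <- voxel_to_physical(moving, corner_idx %*% diag(gm$dim - 1))
  if (any(apply(fc, 2, min) > apply(mc, 2, max)) ||
      any(apply(fc, 2, max) < apply(mc, 2, min)))
    stop("registration error: volumes do not overlap physically",
         call. = FALSE)

  # draw metric samples from a private RNG stream; leave the caller's
  # global RNG state untouched
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  total_iter <- 0L
  converged <- FALSE
  fmetric <- NA_real_
  for (level in seq(settings$n_levels, 1L)) {
    fac <- 2L^(level - 1L)
    fvol <- pyramid_level(fixed, fac)
    d <- dim(fvol$voxels)
    n_avail <- prod(d)
    ns <- min(settings$n_samples, n_avail)
    set.seed(settings$sampling_seed + level)
    sel <- sample.int(n_avail, ns) - 1L
    idx0 <- cbind(sel %% d[1],
                  (sel %/% d[1]) %% d[2],
                  sel %/% (d[1] * d[2]))
    # jitter samples off the voxel lattice: on-grid sampling makes mutual
    # information artificially sharp at integer-voxel offsets (the
    # interpolation artifact), which can trap the optimiser one voxel away
    # from the true alignment
    jit <- matrix(stats::runif(3 * ns, -0.49, 0.49), ncol = 3)
    idxj <- pmin(pmax(idx0 + jit, 0),
                 matrix(rep(d - 1, each = ns), ncol = 3))
    # keep only samples comfortably inside the grid: samples that slide
    # off the moving volume as the transform changes shrink the overlap
    # and bias mutual information toward larger offsets
    margin <- pmin(ceiling(settings$sample_margin_mm / fvol$spacing),
                   (d - 1) %/% 4)
    core <- rowSums(sweep(idxj, 2, margin, "<") |
                      sweep(idxj, 2, d - 1 - margin, ">")) == 0
    if (sum(core) >= 1000L) idxj <- idxj[core, , drop = FALSE]
    fpts <- voxel_to_physical(fvol, idxj)
    fvals <- cpp_interp_points(fvol$voxels, d, idxj, 0)
    frange <- range(fvals)
    mvol <- pyramid_level(moving, fac)
    gm <- volume_geometry(mvol)
    mrange <- range(mvol$voxels)

    metric <- function(x) {
      cpp_mi_neg(fvals, fpts, mvol$voxels, gm$dim, gm$spacing, gm$origin,
                 t(gm$direction),
                 rotation_matrix(x[1:3] / settings$rotation_scale),
                 x[4:6], center, settings$n_bins,
                 frange[1], frange[2], mrange[1], mrange[2])
    }

    min_step <- settings$min_step
    h <- 0.1 * fac
    f0 <- metric(x0)
    iters <- 0L
    # regular-step gradient descent with a restart schedule: a single
    # shrinking step length can collapse on oscillations in well-informed
    # parameters before weakly-informed ones (e.g. translation along an
    # axis of near-invariance) have been walked in, so after each
    # convergence the step is re-armed at a finer scale until no further
    # improvement is found
    for (restart in 1:4) {
      step <- settings$initial_step * fac / 2^(restart - 1)
      prev_dir <- NULL
      f_start <- f0
      while (iters < settings$max_iterations * restart && step > min_step) {
        iters <- iters + 1L
        g <- vapply(1:6, function(a) {
          e <- numeric(6); e[a] <- h
          (metric(x0 + e) - metric(x0 - e)) / (2 * h)
        }, 0)
        gn <- sqrt(sum(g^2))
        if (gn < 1e-12) break
        dir <- -g / gn
        if (!is.null(prev_dir) && sum(dir * prev_dir) < 0)
          step <- step / 2
        if (step <= min_step) break
        x1 <- x0 + step * dir
        f1 <- metric(x1)
        if (f1 < f0) {
          x0 <- x1; f0 <- f1; prev_dir <- dir
          # re-grow the step after success: with strongly anisotropic
          # curvature the step otherwise collapses on the stiff
          # parameters and crawls along the soft ones
          step <- min(step * 1.5, settings$initial_step * fac)
        } else {
          step <- step / 2
          prev_dir <- NULL
        }
      }
      if (step <= min_step || sqrt(sum(g^2)) < 1e-12) converged <- TRUE
      if (f_start - f0 < 1e-7) break
    }
    total_iter <- total_iter + iters
    fmetric <- f0
  }
  structure(list(
    transform = rigid_transform(rotation = x0[1:3] / settings$rotation_scale,
                                translation = x0[4:6], center = center),
    final_metric = fmetric,
    iterations_run = max(total_iter, 1L),
    converged = converged,
    sampling_seed = settings$sampling_seed), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> metric=%.5f, iterations=%d, %s\n",
              x$final_metric, x$iterations_run,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}
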