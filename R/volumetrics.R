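#' Physical volume of a mask
#'
#' True-voxel count times the voxel volume (product of the spacing
#' components), in mm^3. Additive over disjoint masks.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask_voxel_count(mask) * prod(mask$geometry$spacing)
}

#' Stone and collecting-system volumetrics
#'
#' Computes the method's quantitative outputs: stone volume (SV) from the
#' calculus mask, pelvicalyceal-system volume (PSV) from the
#' collecting-system mask, and the SV/PSV stone-burden ratio.
#'
#' Because the delayed intensity band contains stone intensities, a stone
#' inside the collecting system is part of the segmented collecting-system
#' mask. The \code{psv_convention} decides how that is counted:
#' \describe{
#'   \item{union (default)}{PSV is the collecting-system mask as segmented;
#'     stone voxels inside it count toward PSV (the whole urine-space
#'     cavity).}
#'   \item{exclusive}{PSV is the collecting-system mask minus the calculus
#'     mask (contrast-filled space only).}
#' }
#'
#' @param result a \code{segmentation_result} from
#'   \code{\link{run_full_pipeline}}, or any list with
#'   \code{collecting_system} and \code{calculus} masks.
#' @param psv_convention \code{"union"} or \code{"exclusive"}.
#' @return a \code{volume_metrics}: list with \code{SV}, \code{PSV} (mm^3),
#'   \code{ratio} (NA when PSV = 0), \code{psv_convention},
#'   \code{voxel_counts}.
#' @export
compute_metrics <- function(result, psv_convention = c("union", "exclusive")) {
  psv_convention <- match.arg(psv_convention)
  calculus <- result$calculus
  cs <- result$collecting_system
  stopifnot(inherits(calculus, "binary_mask"), inherits(cs, "binary_mask"))
  psv_mask <- if (psv_convention == "union") cs else
    subtract_masks(cs, calculus, label = "collecting_system_excl_stone")
  sv <- mask_volume_mm3(calculus)
  psv <- mask_volume_mm3(psv_mask)
  ratio <- if (psv > 0) sv / psv else NA_real_
  structure(list(
    SV = sv, PSV = psv, ratio = ratio, psv_convention = psv_convention,
    voxel_counts = c(calculus = mask_voxel_count(calculus),
                     collecting_system = mask_voxel_count(cs),
                     psv_mask = mask_voxel_count(psv_mask))),
    class = "volume_metrics")
}

#' @export
print.volume_metrics <- function(x, ...) {
  cat(sprintf("<volume_metrics> SV = %.2f mm^3 (%.3f cm^3)\n", x$SV,
              x$SV / 1000))
  cat(sprintf("  PSV = %.2f mm^3 (%.3f cm^3), convention '%s'\n", x$PSV,
              x$PSV / 1000, x$psv_convention))
  cat(sprintf("  SV/PSV ratio = %s\n",
              if (is.na(x$ratio)) "undefined (PSV = 0)"
              else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Assemble a metrics report
#'
#' Carrier for SV/PSV reporting: metrics, the configuration snapshot they
#' were produced under, per-mask voxel counts, and provenance.
#'
#' @param metrics a \code{volume_metrics}.
#' @param config the \code{\link{segmentation_config}} used.
#' @param provenance named list of input identifiers; the package version
#'   is added automatically.
#' @return a \code{metrics_report}.
#' @export
metrics_report <- function(metrics, config, provenance = list()) {
  stopifnot(inherits(metrics, "volume_metrics"))
  if (!inherits(config, "segmentation_config"))
    stop("validation error: report requires a segmentation_config snapshot",
         call. = FALSE)
  vv <- metrics$voxel_counts
  structure(list(
    metrics = list(SV_mm3 = metrics$SV, PSV_mm3 = metrics$PSV,
                   SV_cm3 = metrics$SV / 1000, PSV_cm3 = metrics$PSV / 1000,
                   ratio = metrics$ratio,
                   psv_convention = metrics$psv_convention),
    config_used = unclass(config),
    voxel_counts = as.list(vv),
    provenance = c(provenance,
                   list(software = paste0("renalseg ",
                                          as.character(packageVersion("renalseg")))))),
    class = "metrics_report")
}

#' Write a metrics report as JSON
#'
#' @param report a \code{\link{metrics_report}}.
#' @param file_path output path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(report, file_path) {
  if (!inherits(report, "metrics_report"))
    stop("validation error: not a metrics_report", call. = FALSE)
  ok <- tryCatch({
    jsonlite::write_json(unclass(report), file_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop(sprintf("I/O error: cannot write %s", file_path), call. = FALSE)
  invisible(file_path)
}

#' Read a metrics report written by \code{write_metrics}
#'
#' @param file_path path to the JSON report.
#' @return a \code{metrics_report}.
#' @export
read_metrics <- function(file_path) {
  x <- jsonlite::read_json(file_path, simplifyVector = TRUE)
  if (is.null(x$config_used))
    stop("validation error: report lacks config snapshot", call. = FALSE)
  structure(x, class = "metrics_report")
}
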