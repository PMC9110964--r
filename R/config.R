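#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their method defaults,
#' grouped by stage. Serialisable to/from JSON with
#' \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  rs <- register_settings()
  list(
    preprocess = list(
      band_shift = list(input_low = -548, input_high = 800,
                        output_low = 0, output_high = 255),
      median_radius = 1L,
      register = rs),
    segmentation = unclass(segmentation_config()),
    volumetrics = list(psv_convention = "union"),
    meshing = list(iso_level = 0.5, smooth_sigma = 0.7,
                   stl_dialect = "binary"))
}

#' Read a configuration file
#'
#' JSON configuration; keys missing from the file keep their defaults.
#'
#' @param file_path path to a JSON config file.
#' @return nested named list as \code{\link{default_config}}.
#' @export
read_config <- function(file_path) {
  if (!file.exists(file_path))
    stop(sprintf("I/O error: config file not found: %s", file_path),
         call. = FALSE)
  user <- jsonlite::read_json(file_path, simplifyVector = TRUE)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Write a configuration file
#'
#' @param config nested list as \code{\link{default_config}}.
#' @param file_path output JSON path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, file_path) {
  jsonlite::write_json(config, file_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file_path)
}

config_to_objects <- function(config) {
  bs <- config$preprocess$band_shift
  list(
    shift = band_shift_spec(bs$input_low, bs$input_high, bs$output_low,
                            bs$output_high),
    median_radius = config$preprocess$median_radius,
    register = do.call(register_settings, config$preprocess$register),
    segmentation = do.call(segmentation_config, config$segmentation),
    psv_convention = config$volumetrics$psv_convention,
    meshing = config$meshing)
}
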