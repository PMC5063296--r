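# NIfTI-1 image/mask I/O, YAML configuration round-trip and study artifacts.

#' Read / write image volumes as NIfTI-1
#'
#' Images are stored as 3-D NIfTI-1 with voxel spacing in mm in the header
#' (RAS+ orientation, float64 data so that write-read round-trips are
#' bit-exact); masks as uint8 label maps.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an `image_volume`; `read_mask()` a
#'   `voi_mask`.
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L) {
    abort("expected a 3-D NIfTI volume.", class = "pethet_format_error")
  }
  spacing <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("missing or invalid voxel spacing.", class = "pethet_format_error")
  }
  image_volume(array(as.numeric(arr), dim(arr)), spacing)
}

#' @param v An `image_volume`.
#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "image_volume"))
  arr <- v$data
  attr(arr, "pixdim") <- v$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  new_voi_mask(array(v$data != 0, dim(v$data)), v$spacing)
}

#' @param mask A `voi_mask`.
#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  arr <- array(as.integer(mask$data), dim(mask$data))
  attr(arr, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Save / load a study configuration as YAML
#'
#' The YAML round-trip is loss-free: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$settings <- as.list(as.data.frame(x$settings))
  x$scanners <- as.list(as.data.frame(x$scanners))
  x$selection <- unclass(x$selection)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$settings <- as_tibble(x$settings)
  x$scanners <- as_tibble(x$scanners)
  do.call(study_config, c(
    x[setdiff(names(x), "selection")],
    list(selection = do.call(selection_config, x$selection))
  ))
}

write_study_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$curves,
    file.path(out_dir, "volume_curves.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$categories,
    file.path(out_dir, "volume_categories.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$repro,
    file.path(out_dir, "reproducibility_cv.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$profiles,
    file.path(out_dir, "sensitivity_profiles.csv"),
    row.names = FALSE
  )
  write_config(result$config, file.path(out_dir, "config.yaml"))
  report <- list(
    seed = result$config$seed,
    selected = as.list(result$report$selected),
    counts = as.list(glance(result$report)),
    verdicts = result$report$verdicts
  )
  jsonlite::write_json(report, file.path(out_dir, "selection_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
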