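# Ground-truth activity maps for the three phantom experiments.
#
# An activity_map holds a 3-D grid of activity concentration (kBq/ml), a
# per-voxel isotope code (1 = F-18, 2 = C-11), a compartment label grid
# (0 outside, 1 background/body, 2.. the syringes) and a reference time in
# minutes at which the concentrations are stated.

ISOTOPES <- c(F18 = 1L, C11 = 2L)

new_activity_map <- function(activity, isotope, regions, spacing, ref_time = 0) {
  stopifnot(
    is.array(activity), length(dim(activity)) == 3L,
    all(dim(isotope) == dim(activity)), all(dim(regions) == dim(activity)),
    length(spacing) == 3L, all(spacing > 0), all(activity >= 0)
  )
  structure(
    list(
      activity = activity, isotope = isotope, regions = regions,
      spacing = as.numeric(spacing), ref_time = ref_time
    ),
    class = "activity_map"
  )
}

#' @export
print.activity_map <- function(x, ...) {
  cat(
    "<activity_map> ", paste(dim(x$activity), collapse = " x "),
    " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
    " mm, t = ", x$ref_time, " min\n",
    sep = ""
  )
  invisible(x)
}

#' Reconstructed (or simulated) PET image volume
#'
#' Light container for a 3-D grid of image values (kBq/ml or SUV g/cm^3) with
#' its voxel spacing in mm and a provenance list recording how it was made.
#'
#' @param data 3-D numeric array of voxel values.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param provenance Optional list (acquisition setting, seed, frame time).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.", class = "pethet_format_error")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.",
      class = "pethet_format_error"
    )
  }
  if (any(!is.finite(data))) {
    abort("image values must be finite.", class = "pethet_format_error")
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), provenance = provenance),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(
    "<image_volume> ", paste(dim(x$data), collapse = " x "),
    " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

# grid dimensions that contain a physical extent (mm) with a margin on each side
auto_grid_dim <- function(extent_mm, voxel_mm, margin_mm) {
  as.integer(ceiling((extent_mm + 2 * margin_mm) / voxel_mm))
}

#' Build the homogeneous cylinder phantom
#'
#' Ground-truth activity map of a uniformly filled cylinder (axis along z),
#' the phantom used for the volume-dependence experiment: a 20 cm diameter
#' cylinder at 5 kBq/ml of F-18.
#'
#' @param diameter_mm,length_mm Cylinder diameter and length in mm.
#' @param activity_kbq_ml Activity concentration inside the cylinder (kBq/ml).
#' @param voxel_mm Isotropic voxel size of the ground-truth grid (mm).
#' @param margin_mm Empty margin around the cylinder on each side (mm).
#' @param dim Optional explicit grid dimensions; it is an error if the grid
#'   cannot contain the cylinder.
#' @return An `activity_map`.
#' @export
#' @examples
#' ph <- build_homogeneous_cylinder(diameter_mm = 60, length_mm = 60, voxel_mm = 4)
#' range(ph$activity)
build_homogeneous_cylinder <- function(diameter_mm = 200, length_mm = 200,
                                       activity_kbq_ml = 5, voxel_mm = 2,
                                       margin_mm = 16, dim = NULL) {
  stopifnot(diameter_mm > 0, length_mm > 0, activity_kbq_ml >= 0, voxel_mm > 0)
  extent <- c(diameter_mm, diameter_mm, length_mm)
  if (is.null(dim)) {
    dim <- auto_grid_dim(extent, voxel_mm, margin_mm)
  } else if (any(dim * voxel_mm < extent)) {
    abort("grid too small to contain the cylinder.", class = "pethet_geometry_error")
  }
  spacing <- rep(voxel_mm, 3)
  co <- grid_coords(dim, spacing)
  inside <- (co$x^2 + co$y^2 <= (diameter_mm / 2)^2) & abs(co$z) <= length_mm / 2
  activity <- array(0, dim)
  activity[inside] <- activity_kbq_ml
  regions <- array(0L, dim)
  regions[inside] <- 1L
  isotope <- array(ISOTOPES[["F18"]], dim)
  new_activity_map(activity, isotope, regions, spacing)
}

#' Build the seven-syringe "Revolver" heterogeneity phantom
#'
#' Ground-truth activity map of the custom insert: seven parallel 3 ml
#' syringes (inner diameter 8.66 mm, length ~50.9 mm, axes along z), one at
#' the centre and six on a ring, inside a background-filled body.  The default
#' activities reproduce the replicated reproducibility experiment (centre
#' syringe 80, two at 40, three at 20 kBq/ml and one left at background, all
#' F-18 over a 5 kBq/ml background).  Setting `syringe_isotopes` to a mix of
#' `"C11"` and `"F18"` builds the dual-isotope sensitivity phantom.
#'
#' @param syringe_activities Seven activity concentrations (kBq/ml); element 1
#'   is the central syringe, elements 2..7 the ring positions.
#' @param syringe_isotopes Seven isotope labels, `"F18"` or `"C11"`.
#' @param background_kbq_ml Background activity of the body (kBq/ml, F-18).
#' @param voxel_mm Isotropic ground-truth voxel size (mm).
#' @param body Body shape hosting the insert: a NEMA-IQ-like elliptical
#'   cylinder (230 x 150 mm cross-section) or a plain circular cylinder.
#' @param body_diameter_mm Diameter of the `"cylinder"` body (mm).
#' @param body_length_mm Axial length of the body (mm).
#' @param ring_radius_mm Centre-to-centre radius of the syringe ring (mm).
#' @param margin_mm Empty margin outside the body (mm).
#' @return An `activity_map`; `regions` labels the body as 1 and the syringes
#'   as 2..8 in the order of `syringe_activities`.
#' @export
#' @examples
#' ph <- build_revolver_phantom(voxel_mm = 4, body = "cylinder",
#'                              body_diameter_mm = 100, body_length_mm = 80)
#' table(ph$regions)
build_revolver_phantom <- function(syringe_activities = c(80, 40, 40, 20, 20, 20, 5),
                                   syringe_isotopes = rep("F18", 7),
                                   background_kbq_ml = 5,
                                   voxel_mm = 2,
                                   body = c("nema", "cylinder"),
                                   body_diameter_mm = 140,
                                   body_length_mm = 120,
                                   ring_radius_mm = 12,
                                   margin_mm = 10) {
  body <- match.arg(body)
  if (length(syringe_activities) != 7L) {
    abort("exactly 7 syringe activities are required.", class = "pethet_geometry_error")
  }
  if (length(syringe_isotopes) != 7L || !all(syringe_isotopes %in% names(ISOTOPES))) {
    abort("syringe_isotopes must be 7 labels in {F18, C11}.", class = "pethet_geometry_error")
  }
  stopifnot(all(syringe_activities >= 0), background_kbq_ml >= 0, voxel_mm > 0)

  syr_radius <- 8.66 / 2
  syr_length <- 3000 / (pi * syr_radius^2) # 3 ml bore -> ~50.93 mm
  if (ring_radius_mm < 2 * syr_radius) {
    abort("ring radius too small: syringes overlap.", class = "pethet_geometry_error")
  }
  ang <- seq(0, 300, by = 60) * pi / 180
  centers <- rbind(c(0, 0), cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang)))

  semi <- switch(body,
    nema = c(115, 75),
    cylinder = rep(body_diameter_mm / 2, 2)
  )
  extent <- c(2 * semi, body_length_mm)
  dim <- auto_grid_dim(extent, voxel_mm, margin_mm)
  spacing <- rep(voxel_mm, 3)
  co <- grid_coords(dim, spacing)

  in_body <- (co$x / semi[1])^2 + (co$y / semi[2])^2 <= 1 & abs(co$z) <= body_length_mm / 2
  activity <- array(0, dim)
  regions <- array(0L, dim)
  isotope <- array(ISOTOPES[["F18"]], dim)
  activity[in_body] <- background_kbq_ml
  regions[in_body] <- 1L

  for (k in 1:7) {
    in_syr <- (co$x - centers[k, 1])^2 + (co$y - centers[k, 2])^2 <= syr_radius^2 &
      abs(co$z) <= syr_length / 2
    if (any(regions[in_syr] > 1L)) {
      abort("syringes overlap on the voxel grid.", class = "pethet_geometry_error")
    }
    if (!all(in_body[in_syr])) {
      abort("a syringe falls outside the body.", class = "pethet_geometry_error")
    }
    activity[in_syr] <- syringe_activities[k]
    regions[in_syr] <- k + 1L
    isotope[in_syr] <- ISOTOPES[[syringe_isotopes[k]]]
  }
  new_activity_map(activity, isotope, regions, spacing)
}

#' Decay an activity map to a later time
#'
#' Scales every voxel by `2^(-dt / T_half)` using the physical half-life of
#' its isotope (F-18: 109.77 min, C-11: 20.36 min).  This is raw physical
#' decay; scanner-style F-18 decay correction is applied later by
#' [simulate_pet_image()].
#'
#' @param map An `activity_map`.
#' @param t_min Target time in minutes; must be `>= map$ref_time`.
#' @return The decayed `activity_map` with `ref_time = t_min`.
#' @export
decay_to_time <- function(map, t_min) {
  stopifnot(inherits(map, "activity_map"))
  dt <- t_min - map$ref_time
  if (dt < 0) abort("cannot decay to an earlier time.", class = "pethet_geometry_error")
  if (dt == 0) return(map)
  codes <- unique(as.integer(map$isotope))
  if (!all(codes %in% ISOTOPES)) {
    abort("unknown isotope code in activity map.", class = "pethet_geometry_error")
  }
  fac <- array(1, dim(map$activity))
  for (iso in names(ISOTOPES)) {
    sel <- map$isotope == ISOTOPES[[iso]]
    fac[sel] <- 2^(-dt / HALF_LIFE[[iso]])
  }
  map$activity <- map$activity * fac
  map$ref_time <- t_min
  map
}
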