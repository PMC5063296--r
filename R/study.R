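# End-to-end study: the three phantom experiments feeding the three-stage
# selection, deterministic given one master seed.

#' Study configuration
#'
#' All parameters of the full phantom study, with defaults mirroring the
#' published design: a 20 cm homogeneous cylinder at 5 kBq/ml probed by
#' spherical VOIs from 0.5 to 1000 ml; the Revolver insert
#' (80/40/40/20/20/20/background kBq/ml) in a NEMA-IQ-like body, imaged in
#' triplicate for every combination of 6 reconstruction settings and
#' acquisition times of 60/120/180/240 s; and a 20-frame, 80-minute
#' dual-isotope series (C-11 syringes at 80, F-18 at 40 kBq/ml at the series
#' start).
#'
#' @param seed Master seed; every stochastic stage derives sub-seeds from it.
#' @param voxel_mm Ground-truth grid voxel size (mm).
#' @param levels Grey levels for the texture resampling.
#' @param volumes_ml Spherical-VOI volume grid (ml).
#' @param scanners Routine protocols of the systems used for the
#'   volume-dependence experiment, see [scanner_protocols()].
#' @param clinical_acq_time_s Acquisition time of the routine protocol used
#'   for the dynamic experiment (s).
#' @param acq_times_s Acquisition-time grid of the reproducibility study (s).
#' @param settings Reconstruction settings tibble, see [recon_settings()].
#' @param n_replicates Independent replicate scans per cell.
#' @param noise_scale Noise scale constant of the simulator.
#' @param nonuniformity_amp Systematic non-uniformity amplitude of the
#'   emulated scanners (fraction of the local mean).
#' @param frame_times_min Frame start times of the dynamic series (min).
#' @param c11_activity,f18_activity Syringe activities of the dual-isotope
#'   phantom at the series start (kBq/ml).
#' @param seg_threshold Relative segmentation threshold (x background).
#' @param selection A [selection_config()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         voxel_mm = 2,
                         levels = 64,
                         volumes_ml = default_volume_grid(),
                         scanners = scanner_protocols(),
                         clinical_acq_time_s = 120,
                         acq_times_s = c(60, 120, 180, 240),
                         settings = recon_settings(),
                         n_replicates = 3L,
                         noise_scale = 4.7,
                         nonuniformity_amp = 0.05,
                         frame_times_min = seq(0, 76, by = 4),
                         c11_activity = 80,
                         f18_activity = 40,
                         seg_threshold = 2.5,
                         selection = selection_config()) {
  if (nrow(settings) == 0L) {
    abort("settings grid must not be empty.", class = "pethet_setting_error")
  }
  if (length(acq_times_s) == 0L || any(acq_times_s <= 0)) {
    abort("acquisition times must be positive.", class = "pethet_setting_error")
  }
  stopifnot(n_replicates >= 2L, length(frame_times_min) > 0L)
  structure(
    list(
      seed = as.integer(seed), voxel_mm = voxel_mm, levels = levels,
      volumes_ml = volumes_ml, scanners = scanners,
      clinical_acq_time_s = clinical_acq_time_s,
      acq_times_s = acq_times_s, settings = settings,
      n_replicates = as.integer(n_replicates), noise_scale = noise_scale,
      nonuniformity_amp = nonuniformity_amp,
      frame_times_min = frame_times_min,
      c11_activity = c11_activity, f18_activity = f18_activity,
      seg_threshold = seg_threshold, selection = selection
    ),
    class = "study_config"
  )
}

# bounding box of the revolver insert (world mm), padded for blur
revolver_box <- function(pad_mm = 8) {
  r <- 12 + 8.66 / 2
  hz <- 3000 / (pi * (8.66 / 2)^2) / 2
  list(
    lower = -c(r + pad_mm, r + pad_mm, hz + pad_mm),
    upper = c(r + pad_mm, r + pad_mm, hz + pad_mm)
  )
}

# phantom-interior mask on the image grid of a simulated cylinder
cylinder_interior <- function(image, diameter_mm, length_mm) {
  co <- grid_coords(dim(image$data), image$spacing)
  array(
    co$x^2 + co$y^2 <= (diameter_mm / 2)^2 & abs(co$z) <= length_mm / 2,
    dim(image$data)
  )
}

#' Routine protocols of the three emulated scanner systems
#'
#' The volume-dependence experiment images the homogeneous cylinder on three
#' different PET/CT systems, each with its routine whole-body protocol; the
#' category fit pools the three curves.  The three protocols are emulated as
#' mild variations of PSF, post-filter and bed time around a typical
#' clinical operating point.
#'
#' @return A tibble with one row per scanner.
#' @export
scanner_protocols <- function() {
  tibble(
    scanner = c("S1", "S2", "S3"),
    psf_fwhm_mm = c(6.5, 7.0, 6.0),
    postfilter_fwhm_mm = c(6, 6.5, 5),
    voxel_mm = c(4, 4, 4),
    acq_time_s = c(180, 180, 120)
  )
}

run_volume_stage <- function(config, seeds) {
  map <- build_homogeneous_cylinder(voxel_mm = config$voxel_mm)
  sc <- config$scanners
  curves <- purrr::map2(seq_len(nrow(sc)), seeds, function(k, seed_k) {
    st <- acquisition_setting(
      acq_time_s = sc$acq_time_s[k], psf_fwhm_mm = sc$psf_fwhm_mm[k],
      postfilter_fwhm_mm = sc$postfilter_fwhm_mm[k], voxel_mm = sc$voxel_mm[k],
      noise_scale = config$noise_scale,
      nonuniformity_amp = config$nonuniformity_amp,
      seed = seed_k, label = sc$scanner[k]
    )
    img <- simulate_pet_image(map, st)
    within <- cylinder_interior(img, 200, 200)
    cv <- volume_dependence_curves(img,
      volumes_ml = config$volumes_ml,
      levels = config$levels, within = within
    )
    dplyr::mutate(cv, scanner = sc$scanner[k])
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("volume_curves", setdiff(class(out), "volume_curves"))
  out
}

run_repro_stage <- function(config, seeds) {
  map <- build_revolver_phantom(voxel_mm = config$voxel_mm)
  grid <- tidyr::expand_grid(
    setting = config$settings$setting,
    acq_time_s = config$acq_times_s,
    replicate = seq_len(config$n_replicates)
  )
  box <- revolver_box()
  rows <- purrr::pmap(
    list(grid$setting, grid$acq_time_s, grid$replicate, seeds),
    function(set_label, t_acq, rep_k, seed_k) {
      row <- config$settings[config$settings$setting == set_label, ]
      st <- acquisition_setting(
        acq_time_s = t_acq, psf_fwhm_mm = row$psf_fwhm_mm,
        postfilter_fwhm_mm = row$postfilter_fwhm_mm, voxel_mm = row$voxel_mm,
        noise_scale = config$noise_scale,
        nonuniformity_amp = config$nonuniformity_amp,
        seed = seed_k, label = set_label
      )
      img <- simulate_pet_image(map, st)
      voi <- threshold_segment(img,
        mode = "relative", threshold = config$seg_threshold, box = box
      )
      ft <- compute_all_features(img, voi, config$levels)
      dplyr::mutate(ft, setting = set_label, acq_time_s = t_acq, replicate = rep_k)
    }
  )
  dplyr::bind_rows(rows)
}

run_sensitivity_stage <- function(config, seed) {
  iso <- rep("F18", 7)
  act <- rep(config$f18_activity, 7)
  c11_pos <- c(1, 2, 4, 6) # centre + alternating ring positions
  iso[c11_pos] <- "C11"
  act[c11_pos] <- config$c11_activity
  map <- build_revolver_phantom(
    syringe_activities = act, syringe_isotopes = iso,
    voxel_mm = config$voxel_mm, body = "cylinder",
    body_diameter_mm = 140, body_length_mm = 120
  )
  st <- acquisition_setting(
    acq_time_s = config$clinical_acq_time_s,
    noise_scale = config$noise_scale,
    nonuniformity_amp = config$nonuniformity_amp,
    seed = seed, label = "dynamic"
  )
  series <- simulate_dynamic_series(map, config$frame_times_min, st)
  box <- revolver_box()
  # equilibrium frame: minimal in-VOI CoV with a per-frame provisional VOI
  cov_by_frame <- purrr::map_dbl(series, function(img) {
    voi <- threshold_segment(img,
      mode = "relative", threshold = config$seg_threshold, box = box
    )
    coefficient_of_variation(img, voi)
  })
  eq <- which.min(cov_by_frame)
  mask <- threshold_segment(series[[eq]],
    mode = "relative", threshold = config$seg_threshold, box = box
  )
  prof <- sensitivity_profiles(series, mask, config$levels)
  list(profiles = prof, mask = mask, equilibrium_frame = eq)
}

#' Run the full three-phantom selection study
#'
#' Executes the volume-dependence, reproducibility and sensitivity
#' experiments end to end and applies the conjunctive selection.
#' Deterministic given the master seed in `config`.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, curves, CV grids, profiles
#'   (CSV) and the selection report (JSON) are written there.
#' @return A list of class `study_result`: `curves`, `categories`,
#'   `replicate_features`, `repro`, `profiles`, `scores`,
#'   `equilibrium_frame`, `report` (a `selection_report`) and `config`.
#' @export
run_full_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  n_scanners <- nrow(config$scanners)
  n_cells <- nrow(config$settings) * length(config$acq_times_s) * config$n_replicates
  seeds <- derive_seeds(config$seed, n_scanners + n_cells + 1L)
  curves <- run_volume_stage(config, seeds[seq_len(n_scanners)])
  categories <- categorize_volume_curves(
    curves,
    v_min_ml = config$selection$v_min_ml,
    slope_tol = config$selection$slope_tol,
    r2_min = config$selection$r2_min
  )
  replicate_features <- run_repro_stage(config, seeds[n_scanners + seq_len(n_cells)])
  repro <- reproducibility_analysis(replicate_features)
  sens <- run_sensitivity_stage(config, seeds[n_scanners + n_cells + 1L])
  scores <- sensitivity_score(sens$profiles, hom_frame = sens$equilibrium_frame)
  report <- select_parameters(categories, repro, scores, config$selection)
  result <- structure(
    list(
      curves = curves, categories = categories,
      replicate_features = replicate_features, repro = repro,
      profiles = sens$profiles, scores = scores,
      equilibrium_frame = sens$equilibrium_frame,
      report = report, config = config
    ),
    class = "study_result"
  )
  if (!is.null(out_dir)) write_study_artifacts(result, out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> master seed ", x$config$seed, "\n", sep = "")
  print(x$report)
  invisible(x)
}
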