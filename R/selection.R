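# The three-criterion evaluation: volume-dependence categorisation on the
# homogeneous phantom, replicate reproducibility on the triplicate Revolver
# grid, sensitivity on the dual-isotope dynamic series, and the conjunctive
# final selection.

default_volume_grid <- function(n = 20) {
  exp(seq(log(0.5), log(1000), length.out = n))
}

#' Volume-dependence curves on the homogeneous phantom
#'
#' Computes every heterogeneity parameter on concentric spherical VOIs
#' (default log-spaced 0.5 to 1000 ml) centred in a homogeneous-phantom
#' image, giving one (volume, value) curve per parameter.
#'
#' @param image An `image_volume` of the homogeneous phantom.
#' @param center_mm Common VOI centre in world mm.
#' @param volumes_ml VOI volumes in ml; sorted internally.
#' @param levels Grey levels for the resampling.
#' @param within Optional logical array bounding the phantom interior; VOIs
#'   must stay inside it.
#' @return A tibble of class `volume_curves` with columns `parameter`,
#'   `volume_ml`, `value` (volumes strictly increasing within parameter).
#' @export
volume_dependence_curves <- function(image, center_mm = c(0, 0, 0),
                                     volumes_ml = default_volume_grid(),
                                     levels = 64, within = NULL) {
  volumes_ml <- sort(unique(volumes_ml))
  rows <- purrr::map(volumes_ml, function(v) {
    voi <- spherical_voi(image, center_mm, v, within = within)
    ft <- compute_all_features(image, voi, levels)
    dplyr::mutate(ft, requested_volume_ml = v)
  })
  curves <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(
      dplyr::all_of(heterogeneity_parameters()),
      names_to = "parameter", values_to = "value"
    ) |>
    dplyr::select(
      parameter = "parameter", volume_ml = "requested_volume_ml",
      value = "value", achieved_volume_ml = "volume_ml", n_voxels = "n_voxels"
    ) |>
    dplyr::arrange(.data$parameter, .data$volume_ml)
  class(curves) <- c("volume_curves", class(curves))
  curves
}

#' Categorise one volume-dependence curve
#'
#' Least-squares line fit to `(log10 V, log10 value)` restricted to
#' `V >= v_min_ml`, classifying the curve as converging (A) when
#' `|slope| <= slope_tol`, positive slope (B) or negative slope (D) when the
#' slope exceeds the tolerance with `R^2 >= r2_min`, and random-like (C)
#' otherwise.  Curves containing non-positive values are shifted by
#' `value - min + 1e-6 * range` before taking logs (flagged in the output).
#'
#' @param curve A tibble with columns `volume_ml` and `value` (one parameter).
#' @param v_min_ml Minimal volume of the fitted (flat) region, in ml.
#' @param slope_tol Absolute log-log slope below which the curve counts as
#'   volume independent.
#' @param r2_min Minimal `R^2` for calling a monotone slope.
#' @return One-row tibble: `category` (`"A"`, `"B"`, `"C"`, `"D"`), `slope`,
#'   `r_squared`, `n_points`, `shifted`.
#' @export
categorize_curve <- function(curve, v_min_ml = 30, slope_tol = 0.05, r2_min = 0.8) {
  cv <- dplyr::filter(curve, .data$volume_ml >= v_min_ml)
  if (nrow(cv) < 4L) {
    abort("need at least 4 points above v_min_ml.", class = "pethet_selection_error")
  }
  y <- cv$value
  shifted <- any(y <= 0)
  if (shifted) {
    rng <- max(y) - min(y)
    y <- y - min(y) + 1e-6 * max(rng, .Machine$double.eps)
  }
  ly <- log10(y)
  lx <- log10(cv$volume_ml)
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot < 1e-24) NA_real_ else 1 - sum(fit$residuals^2) / ss_tot
  category <- if (abs(slope) <= slope_tol) {
    "A"
  } else if (!is.na(r2) && r2 >= r2_min && slope > 0) {
    "B"
  } else if (!is.na(r2) && r2 >= r2_min && slope < 0) {
    "D"
  } else {
    "C"
  }
  tibble(
    category = category, slope = slope, r_squared = r2,
    n_points = nrow(cv), shifted = shifted
  )
}

#' Categorise every parameter's volume-dependence curve
#'
#' @param curves A `volume_curves` tibble from [volume_dependence_curves()].
#' @inheritParams categorize_curve
#' @return A tibble with one row per parameter: `parameter`, `category`,
#'   `slope`, `r_squared`, `n_points`, `shifted`.
#' @export
categorize_volume_curves <- function(curves, v_min_ml = 30, slope_tol = 0.05,
                                     r2_min = 0.8) {
  curves |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~ categorize_curve(.x, v_min_ml, slope_tol, r2_min)) |>
    dplyr::ungroup()
}

#' Replicate reproducibility analysis
#'
#' For each parameter and each (setting, acquisition time) cell, computes the
#' replicate mean, sample standard deviation and coefficient of variation
#' `CV = SD / mean` over the independent replicate scans (three in the
#' published design).
#'
#' @param replicate_features A tibble with columns `setting`, `acq_time_s`,
#'   `replicate` and one column per heterogeneity parameter (the output rows
#'   of [compute_all_features()] plus the three metadata columns).
#' @return A tibble of class `repro_report`: `parameter`, `setting`,
#'   `acq_time_s`, `n`, `mean`, `sd`, `cv`, `degenerate` (`TRUE` where the
#'   replicate mean is 0 and the CV is undefined).
#' @export
reproducibility_analysis <- function(replicate_features) {
  params <- intersect(heterogeneity_parameters(), names(replicate_features))
  if (!length(params)) {
    abort("no heterogeneity parameter columns found.", class = "pethet_selection_error")
  }
  long <- tidyr::pivot_longer(
    replicate_features, dplyr::all_of(params),
    names_to = "parameter", values_to = "value"
  )
  rep <- long |>
    dplyr::group_by(.data$parameter, .data$setting, .data$acq_time_s) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$mean == 0,
      cv = dplyr::if_else(.data$degenerate, NA_real_, abs(.data$sd / .data$mean))
    )
  if (any(rep$n < 2L)) {
    abort("every (setting, time) cell needs at least 2 replicates.",
      class = "pethet_selection_error"
    )
  }
  class(rep) <- c("repro_report", class(rep))
  rep
}

#' Feature time profiles over the dynamic dual-isotope series
#'
#' Computes all parameters on every frame of the series using one fixed VOI
#' (conventionally frozen from the equilibrium frame, where the decaying
#' C-11 and the decay-corrected F-18 syringes have equal apparent activity).
#'
#' @param series List of `image_volume` frames from
#'   [simulate_dynamic_series()].
#' @param mask A single `voi_mask` applied to every frame.
#' @param levels Grey levels for the resampling.
#' @return A tibble of class `sensitivity_profiles`: `frame`, `time_min`,
#'   `parameter`, `value`.
#' @export
sensitivity_profiles <- function(series, mask, levels = 64) {
  if (!length(series)) abort("empty frame series.", class = "pethet_selection_error")
  rows <- purrr::imap(series, function(img, k) {
    ft <- compute_all_features(img, mask, levels)
    t_min <- img$provenance$frame_time_min
    dplyr::mutate(ft, frame = k, time_min = if (is.null(t_min)) NA_real_ else t_min)
  })
  prof <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(
      dplyr::all_of(heterogeneity_parameters()),
      names_to = "parameter", values_to = "value"
    ) |>
    dplyr::select("frame", "time_min", "parameter", "value")
  class(prof) <- c("sensitivity_profiles", class(prof))
  prof
}

#' Locate the equilibrium (most homogeneous) frame
#'
#' The frame whose in-VOI Coefficient of Variation is minimal; never assumed
#' at a fixed time.
#'
#' @param profiles A `sensitivity_profiles` tibble.
#' @return The frame index (integer).
#' @export
equilibrium_frame <- function(profiles) {
  cov <- dplyr::filter(profiles, .data$parameter == "CoV") |>
    dplyr::arrange(.data$frame)
  cov$frame[which.min(cov$value)]
}

#' Sensitivity score of each parameter
#'
#' Relative change between the most heterogeneous and the homogeneous state:
#' `score = |value(het) - value(hom)| / |value(hom)|`, where `hom` is the
#' equilibrium frame and `het` the frame deviating most from it.  A constant
#' (zero-range) profile scores 0.
#'
#' @param profiles A `sensitivity_profiles` tibble.
#' @param hom_frame Equilibrium frame index; located via [equilibrium_frame()]
#'   when `NULL`.
#' @return Tibble `parameter`, `score`, `hom_frame`, `het_frame`.
#' @export
sensitivity_score <- function(profiles, hom_frame = NULL) {
  if (is.null(hom_frame)) hom_frame <- equilibrium_frame(profiles)
  profiles |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      v_hom <- df$value[df$frame == hom_frame]
      dev <- abs(df$value - v_hom)
      k <- which.max(dev)
      score <- if (max(dev) == 0) 0 else dev[k] / max(abs(v_hom), .Machine$double.eps)
      tibble(score = score, hom_frame = hom_frame, het_frame = df$frame[k])
    }) |>
    dplyr::ungroup()
}

#' Selection thresholds
#'
#' @param cv_max Maximal acceptable replicate CV per cell (default 0.10).
#' @param cv_cell_fraction Fraction of (setting, time) cells that must meet
#'   `cv_max` ("almost all", default 0.75).
#' @param s_min Minimal sensitivity score (relative change, default 0.20).
#' @param v_min_ml,slope_tol,r2_min Volume-categorisation cutoffs, see
#'   [categorize_curve()].
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(cv_max = 0.10, cv_cell_fraction = 0.75, s_min = 0.20,
                             v_min_ml = 30, slope_tol = 0.05, r2_min = 0.8) {
  structure(
    list(
      cv_max = cv_max, cv_cell_fraction = cv_cell_fraction, s_min = s_min,
      v_min_ml = v_min_ml, slope_tol = slope_tol, r2_min = r2_min
    ),
    class = "selection_config"
  )
}

#' Final parameter selection
#'
#' Conjunction of the three criteria: a parameter is selected iff its volume
#' curve is category A (converging), its replicate CV is below `cv_max` in at
#' least `cv_cell_fraction` of the (setting, acquisition time) cells, and its
#' sensitivity score reaches `s_min`.
#'
#' @param categories Output of [categorize_volume_curves()].
#' @param repro_report Output of [reproducibility_analysis()].
#' @param sensitivity_scores Output of [sensitivity_score()].
#' @param config A [selection_config()].
#' @return An object of class `selection_report` with elements `verdicts`
#'   (per-parameter tibble), `selected` (character vector) and `config`.
#'   Use [tidy()] / [glance()] to extract tidy summaries.
#' @export
select_parameters <- function(categories, repro_report, sensitivity_scores,
                              config = selection_config()) {
  params <- heterogeneity_parameters()
  missing <- setdiff(
    params,
    Reduce(intersect, list(
      categories$parameter, unique(repro_report$parameter),
      sensitivity_scores$parameter
    ))
  )
  if (length(missing)) {
    abort(
      paste0("missing stage results for: ", paste(missing, collapse = ", ")),
      class = "pethet_selection_error"
    )
  }
  cv_frac <- repro_report |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      frac_cells_ok = mean(!is.na(.data$cv) & .data$cv < config$cv_max),
      worst_cv = max(.data$cv, na.rm = TRUE),
      best_cv = min(.data$cv, na.rm = TRUE),
      .groups = "drop"
    )
  verdicts <- categories |>
    dplyr::select("parameter", "category", "slope", "r_squared") |>
    dplyr::left_join(cv_frac, by = "parameter") |>
    dplyr::left_join(
      dplyr::select(sensitivity_scores, "parameter", sensitivity_score = "score"),
      by = "parameter"
    ) |>
    dplyr::mutate(
      volume_ok = .data$category == "A",
      repro_ok = .data$frac_cells_ok >= config$cv_cell_fraction,
      sensitivity_ok = .data$sensitivity_score >= config$s_min,
      selected = .data$volume_ok & .data$repro_ok & .data$sensitivity_ok
    ) |>
    dplyr::arrange(factor(.data$parameter, levels = params))
  structure(
    list(
      verdicts = verdicts,
      selected = verdicts$parameter[verdicts$selected],
      config = config
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  g <- glance(x)
  cat(
    "<selection_report> ", g$n_parameters, " parameters evaluated; ",
    g$n_volume_independent, " volume independent (category A); ",
    g$n_selected, " selected: ", paste(x$selected, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
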