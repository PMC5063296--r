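# Volume-dependence categorisation, reproducibility CV, sensitivity scoring
# and the conjunctive selection logic.

make_curve <- function(volumes, values) tibble::tibble(volume_ml = volumes, value = values)

test_that("curve categorisation recognises flat, power-law and erratic shapes", {
  v <- exp(seq(log(0.5), log(1000), length.out = 14))
  flat <- categorize_curve(make_curve(v, rep(3.2, 14)))
  expect_equal(flat$category, "A")
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  up <- categorize_curve(make_curve(v, v)) # slope 1 in log-log
  expect_equal(up$category, "B")
  expect_equal(up$slope, 1, tolerance = 1e-10)
  down <- categorize_curve(make_curve(v, 1 / v))
  expect_equal(down$category, "D")
  expect_equal(down$slope, -1, tolerance = 1e-10)
  # erratic: big slope but terrible fit -> random-like
  withr::with_seed(1, {
    y <- rep(2, 14)
    y[v >= 30][c(2, 5)] <- c(40, 0.1) # order-of-magnitude outliers
  })
  err <- categorize_curve(make_curve(v, y))
  expect_equal(err$category, "C")
  expect_lt(err$r_squared, 0.8)
  expect_gt(abs(err$slope), 0.05)
  expect_error(categorize_curve(make_curve(c(50, 100, 200), c(1, 1, 1))),
    class = "pethet_selection_error"
  )
  # non-positive values are shifted, fit still returned
  shifted <- categorize_curve(make_curve(v, rep(0, 14)))
  expect_true(shifted$shifted)
  expect_equal(shifted$category, "A")
})

test_that("category assignment matches constructed power-law exponents", {
  v <- exp(seq(log(0.5), log(1000), length.out = 14))
  for (expo in c(-0.5, -0.1, 0.1, 0.5)) {
    got <- categorize_curve(make_curve(v, v^expo))
    expect_equal(got$category, if (expo > 0) "B" else "D", label = paste("exponent", expo))
  }
})

test_that("reproducibility CV is the replicate SD over mean", {
  ft <- tidyr::expand_grid(
    setting = c("A", "B"), acq_time_s = c(60, 120), replicate = 1:3
  )
  ft$ENT <- rep(c(9, 10, 11), times = 4)
  ft$CoV <- 0.5
  rep <- reproducibility_analysis(ft)
  ent <- dplyr::filter(rep, .data$parameter == "ENT")
  expect_equal(nrow(ent), 4)
  expect_true(all(abs(ent$cv - 0.1) < 1e-12))
  cov <- dplyr::filter(rep, .data$parameter == "CoV")
  expect_true(all(cov$cv == 0))
  # full grid shape: 6 settings x 4 times
  ft2 <- tidyr::expand_grid(
    setting = LETTERS[1:6], acq_time_s = c(60, 120, 180, 240), replicate = 1:3
  )
  ft2$HOM <- runif(nrow(ft2))
  rep2 <- reproducibility_analysis(ft2)
  expect_equal(nrow(rep2), 24)
  # zero-mean cells are flagged, not poisoned
  ft$ENT <- 0
  rep3 <- reproducibility_analysis(ft)
  expect_true(all(dplyr::filter(rep3, .data$parameter == "ENT")$degenerate))
})

test_that("sensitivity scores measure relative change from the equilibrium frame", {
  prof <- tibble::tibble(
    frame = rep(1:10, 2), time_min = rep(seq(0, 36, by = 4), 2),
    parameter = rep(c("CoV", "HOM"), each = 10),
    value = c(c(0.5, 0.4, 0.3, 0.2, 0.1, 0.15, 0.25, 0.35, 0.45, 0.5), rep(0.5, 10))
  )
  class(prof) <- c("sensitivity_profiles", class(prof))
  expect_equal(equilibrium_frame(prof), 5)
  sc <- sensitivity_score(prof)
  expect_equal(sc$score[sc$parameter == "CoV"], 0.4 / 0.1)
  expect_equal(sc$score[sc$parameter == "HOM"], 0) # constant profile
  # the documented worked example: {0.5, ..., 0.5, 0.6} scores 0.2
  prof2 <- tibble::tibble(
    frame = 1:10, time_min = seq(0, 36, 4), parameter = "CoV",
    value = c(rep(0.5, 9), 0.6)
  )
  sc2 <- sensitivity_score(prof2, hom_frame = 1)
  expect_equal(sc2$score, 0.2)
})

test_that("selection is the conjunction of the three criteria", {
  params <- heterogeneity_parameters()
  cats <- tibble::tibble(
    parameter = params,
    category = ifelse(params %in% c("ENT", "COR", "CoV", "HOM", "CON"), "A", "D"),
    slope = 0, r_squared = 1
  )
  repro <- tidyr::expand_grid(
    parameter = params, setting = LETTERS[1:6], acq_time_s = c(60, 120, 180, 240)
  )
  repro$n <- 3L
  repro$mean <- 1
  repro$sd <- ifelse(repro$parameter == "CON", 0.2, 0.01)
  repro$cv <- repro$sd / repro$mean
  repro$degenerate <- FALSE
  scores <- tibble::tibble(
    parameter = params,
    score = ifelse(params == "HOM", 0.05, 0.5),
    hom_frame = 5L, het_frame = 1L
  )
  rep <- select_parameters(cats, repro, scores)
  expect_s3_class(rep, "selection_report")
  # CON fails repro, HOM fails sensitivity, category-D parameters are out
  expect_setequal(rep$selected, c("ENT", "COR", "CoV"))
  v <- tidy(rep)
  expect_false(v$selected[v$parameter == "HOM"])
  expect_true(v$volume_ok[v$parameter == "HOM"])
  expect_false(v$repro_ok[v$parameter == "CON"])
  expect_false(any(v$selected[v$category == "D"]))
  g <- glance(rep)
  expect_equal(g$n_parameters, 27)
  expect_equal(g$n_volume_independent, 5)
  expect_equal(g$n_matrix_converging, 4)
  # tightening any single threshold never grows the set
  for (cfg in list(
    selection_config(cv_max = 0.05),
    selection_config(s_min = 0.6),
    selection_config(cv_cell_fraction = 1)
  )) {
    expect_true(all(select_parameters(cats, repro, scores, cfg)$selected %in% rep$selected))
  }
  # a missing stage is an error
  expect_error(
    select_parameters(cats[-1, ], repro, scores),
    class = "pethet_selection_error"
  )
})

test_that("volume curves on a noise-free homogeneous image are flat and category A", {
  ph <- build_homogeneous_cylinder(diameter_mm = 160, length_mm = 160, voxel_mm = 4)
  st <- noise_free_setting(voxel_mm = 4)
  img <- simulate_pet_image(ph, st)
  within <- pethet:::cylinder_interior(img, 160, 160)
  vols <- exp(seq(log(5), log(200), length.out = 8))
  curves <- volume_dependence_curves(img, volumes_ml = vols, levels = 16, within = within)
  # CoV of a perfectly homogeneous VOI interior is tiny at every volume
  cov <- dplyr::filter(curves, .data$parameter == "CoV")
  expect_true(all(cov$value < 1e-10))
  expect_true(!is.unsorted(cov$volume_ml, strictly = TRUE))
  cats <- categorize_volume_curves(curves, v_min_ml = 20)
  # every constant curve is labelled A (sanity anchor)
  flat <- cats$parameter[abs(cats$slope) < 1e-8]
  expect_true(all(cats$category[cats$parameter %in% flat] == "A"))
  expect_true(all(c("CoV", "ENT", "HOM") %in% flat))
})
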