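# Texture matrices and heterogeneity parameters: hand-computed examples,
# structural invariants and symmetry properties.

test_that("grey-level resampling follows the fixed-bin-number rule with top-bin clip", {
  img <- tiny_image(c(10, 20, 30))
  m <- full_mask(img)
  g <- resample_grey_levels(img, m, levels = 64)
  expect_identical(as.integer(g$data), c(1L, 33L, 64L))
  # minimum maps to 1, constant region maps to all-ones
  expect_equal(g$data[1, 1, 1], 1L)
  gc <- resample_grey_levels(tiny_image(rep(7, 5), c(5, 1, 1)), full_mask(tiny_image(rep(7, 5), c(5, 1, 1))), 64)
  expect_true(all(gc$data == 1L))
  expect_error(
    resample_grey_levels(img, pethet:::new_voi_mask(array(FALSE, c(3, 1, 1)), c(1, 1, 1))),
    class = "pethet_texture_error"
  )
})

test_that("co-occurrence matrix and features match the hand-worked 1-D strip", {
  img <- tiny_image(c(1, 1, 2))
  g <- resample_grey_levels(img, full_mask(img), levels = 2)
  cm <- compute_cooccurrence(g)
  expect_equal(cm$p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(cm$p, t(cm$p))
  f <- cooccurrence_features(cm)
  expect_equal(unname(f["HOM"]), 0.75)
  expect_equal(unname(f["CON"]), 0.5)
  expect_equal(unname(f["ENT"]), 1.5)
  expect_equal(unname(f["COR"]), -1 / 3)
})

test_that("constant regions give the degenerate analytic values", {
  img <- tiny_image(rep(3, 27), c(3, 3, 3))
  m <- full_mask(img)
  g <- resample_grey_levels(img, m, 64)
  f <- cooccurrence_features(compute_cooccurrence(g))
  expect_equal(unname(f["ENT"]), 0)
  expect_equal(unname(f["CON"]), 0)
  expect_equal(unname(f["HOM"]), 1)
  expect_equal(unname(f["COR"]), 0) # sentinel on sigma^2 = 0
  expect_equal(coefficient_of_variation(img, m), 0)
  # single zone of size N_v, single runs per direction
  sz <- compute_sizezone(g)
  expect_equal(sz$n_zones, 1L)
  fz <- sizezone_features(sz)
  expect_equal(unname(fz["LZE"]), 27^2)
  expect_equal(unname(fz["ZP"]), 1 / 27)
  # constant 1-D strip, one direction: LRE = N^2, SRE = 1/N^2, RP = 1/N
  strip <- tiny_image(rep(1, 5))
  gs <- resample_grey_levels(strip, full_mask(strip), 2)
  fr <- runlength_features(compute_runlength(gs, directions = c(1, 0, 0)))
  expect_equal(unname(fr["LRE"]), 25)
  expect_equal(unname(fr["SRE"]), 1 / 25)
  expect_equal(unname(fr["RP"]), 1 / 5)
})

test_that("run-length matrix matches hand enumeration on the 5-voxel strip", {
  img <- tiny_image(c(1, 1, 2, 2, 2))
  g <- resample_grey_levels(img, full_mask(img), 2)
  rl <- compute_runlength(g, directions = c(1, 0, 0))
  expect_equal(rl$n_runs, 2L)
  expect_equal(sum(rl$counts$length * rl$counts$n), 5) # runs partition the strip
  f <- runlength_features(rl)
  expect_equal(unname(f["SRE"]), 13 / 72)
  expect_equal(unname(f["LRE"]), 6.5)
  expect_equal(unname(f["RP"]), 2 / 5)
  expect_equal(unname(f["GLNU_R"]), 1)
})

test_that("size-zone matrix matches hand labelling of the 3x3 slice", {
  img <- tiny_image(c(1, 1, 3, 1, 2, 3, 2, 2, 3), c(3, 3, 1))
  # column-major layout: rows (1,1,2),(1,2,2),(3,3,3) as columns; three zones of 3
  g <- resample_grey_levels(img, full_mask(img), 4)
  sz <- compute_sizezone(g)
  expect_equal(sz$n_zones, 3L)
  expect_true(all(sz$counts$size == 3))
  expect_equal(sum(sz$counts$size * sz$counts$n), 9) # zones partition the mask
  f <- sizezone_features(sz)
  expect_equal(unname(f["SZE"]), 1 / 9)
  expect_equal(unname(f["LZE"]), 9)
  expect_equal(unname(f["ZP"]), 1 / 3)
})

test_that("intensity variability counts zone grey-level non-uniformity", {
  img <- tiny_image(rep(2, 8), c(2, 2, 2))
  g <- resample_grey_levels(img, full_mask(img), 4)
  expect_equal(intensity_variability(compute_sizezone(g)), 1) # single zone
  # two zones of different greys -> 1; two zones of the same grey -> 2
  img2 <- tiny_image(c(1, 1, 2, 2))
  g2 <- resample_grey_levels(img2, full_mask(img2), 2)
  expect_equal(intensity_variability(compute_sizezone(g2)), 1)
  img3 <- tiny_image(c(1, 1, 9, 1, 1), c(5, 1, 1))
  g3 <- resample_grey_levels(img3, full_mask(img3), 2)
  # zones: {1,1}, {9}, {1,1} -> greys (1,2,1): IV = (2^2 + 1^2)/3
  expect_equal(intensity_variability(compute_sizezone(g3)), 5 / 3)
})

test_that("coefficient of variation uses sample SD on raw intensities", {
  img <- tiny_image(c(4, 6))
  expect_equal(coefficient_of_variation(img, full_mask(img)), sqrt(2) / 5)
  # scale invariance
  img2 <- tiny_image(c(4, 6) * 13.7)
  expect_equal(
    coefficient_of_variation(img2, full_mask(img2)),
    coefficient_of_variation(img, full_mask(img))
  )
  neg <- tiny_image(c(-4, -6))
  expect_error(coefficient_of_variation(neg, full_mask(neg)), class = "pethet_texture_error")
})

test_that("compute_all_features returns exactly the 27 named parameters", {
  case <- random_grey_case(11, dim = c(5, 5, 5), levels = 6)
  img <- tiny_image(as.numeric(case$grey), dim(case$grey))
  mask <- pethet:::new_voi_mask(case$mask, c(1, 1, 1))
  ft <- compute_all_features(img, mask, levels = 8)
  expect_setequal(
    setdiff(names(ft), c("volume_ml", "n_voxels")),
    heterogeneity_parameters()
  )
  expect_length(heterogeneity_parameters(), 27)
  expect_true(all(is.finite(unlist(ft))))
  # range invariants
  expect_gte(ft$HOM, 0); expect_lte(ft$HOM, 1)
  expect_gte(ft$COR, -1); expect_lte(ft$COR, 1)
  expect_gte(ft$ENT, 0); expect_gte(ft$CON, 0)
  expect_gt(ft$SRE, 0); expect_lte(ft$SRE, 1)
  expect_gt(ft$SZE, 0); expect_lte(ft$SZE, 1)
  expect_gte(ft$LRE, 1); expect_gte(ft$LZE, 1)
  expect_gt(ft$RP, 0); expect_lte(ft$RP, 1)
  expect_gt(ft$ZP, 0); expect_lte(ft$ZP, 1)
  expect_gte(ft$CoV, 0)
})

test_that("matrix features are invariant under positive affine intensity maps; CoV is not", {
  case <- random_grey_case(7, dim = c(5, 5, 5), levels = 5)
  vals <- withr::with_seed(8, runif(125, 1, 4)) # continuous: no bin-edge ties
  img <- tiny_image(vals, dim(case$grey))
  mask <- pethet:::new_voi_mask(case$mask, c(1, 1, 1))
  ft1 <- compute_all_features(img, mask, levels = 8)
  img2 <- image_volume(img$data * 3.2 + 1.4, img$spacing)
  ft2 <- compute_all_features(img2, mask, levels = 8)
  for (p in heterogeneity_parameters(matrix_only = TRUE)) {
    expect_equal(ft2[[p]], ft1[[p]], tolerance = 1e-12, label = p)
  }
  expect_false(isTRUE(all.equal(ft1$CoV, ft2$CoV)))
})

test_that("grey-level reversal preserves symmetric features and swaps low/high emphasis", {
  case <- random_grey_case(23, dim = c(5, 5, 5), levels = 8)
  g1 <- as_grey_image(case$grey, case$mask, 8)
  g2 <- as_grey_image(8 + 1 - case$grey, case$mask, 8)
  f1c <- cooccurrence_features(compute_cooccurrence(g1))
  f2c <- cooccurrence_features(compute_cooccurrence(g2))
  for (p in c("ENT", "CON", "HOM")) expect_equal(f2c[[p]], f1c[[p]], label = p)
  r1 <- runlength_features(compute_runlength(g1))
  r2 <- runlength_features(compute_runlength(g2))
  for (p in c("SRE", "LRE", "RP")) expect_equal(r2[[p]], r1[[p]], label = p)
  z1 <- sizezone_features(compute_sizezone(g1))
  z2 <- sizezone_features(compute_sizezone(g2))
  for (p in c("SZE", "LZE", "ZP", "SZV")) expect_equal(z2[[p]], z1[[p]], label = p)
  # low/high grey emphasis pairs swap under the reversal i -> L + 1 - i
  rev_i2 <- function(g) {
    cts <- compute_runlength(g)$counts
    sum(cts$n * (8 + 1 - cts$grey)^2) / sum(cts$n)
  }
  expect_equal(unname(r2[["HGLRE"]]), rev_i2(g1))
})

test_that("feature values are deterministic and independent of voxel order", {
  case <- random_grey_case(3, dim = c(4, 4, 4), levels = 4)
  img <- tiny_image(as.numeric(case$grey), dim(case$grey))
  mask <- pethet:::new_voi_mask(case$mask, c(1, 1, 1))
  f1 <- compute_all_features(img, mask, levels = 4)
  f2 <- compute_all_features(img, mask, levels = 4)
  expect_identical(f1, f2)
})

test_that("cooccurrence errors when the mask has no neighbouring pairs", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE
  m[5, 5, 5] <- TRUE
  g <- as_grey_image(array(1L, c(5, 5, 5)), m, 2)
  expect_error(compute_cooccurrence(g), class = "pethet_texture_error")
})
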