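# small in-code fixtures shared across test files

# wrap a numeric vector/array as an image_volume with unit-ish spacing
tiny_image <- function(values, dim = c(length(values), 1, 1), spacing = c(1, 1, 1)) {
  image_volume(array(values, dim), spacing)
}

full_mask <- function(image) {
  pethet:::new_voi_mask(array(TRUE, dim(image$data)), image$spacing)
}

# random masked grey image fixture: values and a mask on a small grid
random_grey_case <- function(seed, dim = c(4, 4, 4), levels = 4, p_mask = 0.85) {
  withr::with_seed(seed, {
    g <- array(sample.int(levels, prod(dim), replace = TRUE), dim)
    m <- array(runif(prod(dim)) < p_mask, dim)
    if (sum(m) < 2) m[1:2] <- TRUE
    list(grey = g, mask = m, levels = levels)
  })
}

# package grey_level_image built directly from integer grid + mask
as_grey_image <- function(g, m, levels) {
  img <- image_volume(array(as.numeric(g), dim(g)), c(1, 1, 1))
  mask <- pethet:::new_voi_mask(m, c(1, 1, 1))
  structure(
    list(
      data = array(as.integer(g * m), dim(g)), mask = m,
      levels = as.integer(levels), min = min(g[m]), max = max(g[m]),
      spacing = c(1, 1, 1)
    ),
    class = "grey_level_image"
  )
}

noise_free_setting <- function(...) {
  acquisition_setting(noise_scale = 0, nonuniformity_amp = 0, ...)
}
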