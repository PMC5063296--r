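# The 27 heterogeneity parameters: four co-occurrence indices, Intensity
# Variability, eleven size-zone indices, ten run-length indices and the
# first-order Coefficient of Variation.

#' Co-occurrence features: HOM, COR, ENT, CON
#'
#' Standard definitions on the direction-averaged probability matrix `p`:
#' Homogeneity `sum p/(1+|i-j|)`, Contrast `sum (i-j)^2 p`, Entropy
#' `-sum p log2 p` (bits), and Correlation
#' `sum (i-mu)(j-mu) p / sigma^2` with `mu`, `sigma^2` the symmetric
#' marginal mean and variance.  On a degenerate (constant-grey) region
#' `sigma^2 = 0` and Correlation returns the sentinel value 0.
#'
#' @param m A `cooccurrence_matrix`.
#' @return Named numeric vector `HOM`, `COR`, `ENT`, `CON`.
#' @export
cooccurrence_features <- function(m) {
  stopifnot(inherits(m, "cooccurrence_matrix"))
  p <- m$p
  i <- row(p)
  j <- col(p)
  hom <- sum(p / (1 + abs(i - j)))
  con <- sum((i - j)^2 * p)
  pp <- p[p > 0]
  ent <- -sum(pp * log2(pp))
  pi_marg <- rowSums(p)
  mu <- sum(seq_len(m$levels) * pi_marg)
  sig2 <- sum((seq_len(m$levels) - mu)^2 * pi_marg)
  cor <- if (sig2 < 1e-12) 0 else (sum(i * j * p) - mu^2) / sig2
  c(HOM = hom, COR = cor, ENT = ent, CON = con)
}

#' Run-length features
#'
#' Normalised sums over the aggregated run counts `r(i, l)` with total run
#' count `N_r`: Short/Long Run Emphasis weight runs by `1/l^2` / `l^2`,
#' Low/High Grey-Level Run Emphasis by `1/i^2` / `i^2`, the four joint
#' variants by both factors, Grey-Level Non-Uniformity is
#' `sum_i (sum_l r)^2 / N_r` and Run Percentage is
#' `N_r / (N_v * directions)`.
#'
#' @param r A `runlength_matrix`.
#' @return Named numeric vector of the ten run-length parameters.
#' @export
runlength_features <- function(r) {
  stopifnot(inherits(r, "runlength_matrix"))
  cts <- r$counts
  i <- cts$grey
  l <- cts$length
  n <- cts$n
  Nr <- r$n_runs
  by_grey <- tapply(n, i, sum)
  c(
    RP = Nr / (r$n_voxels * r$n_directions),
    SRE = sum(n / l^2) / Nr,
    LRE = sum(n * l^2) / Nr,
    GLNU_R = sum(by_grey^2) / Nr,
    LGLRE = sum(n / i^2) / Nr,
    HGLRE = sum(n * i^2) / Nr,
    SRLGLE = sum(n / (i^2 * l^2)) / Nr,
    SRHGLE = sum(n * i^2 / l^2) / Nr,
    LRLGLE = sum(n * l^2 / i^2) / Nr,
    LRHGLE = sum(n * i^2 * l^2) / Nr
  )
}

#' Size-zone features
#'
#' Exact zone analogues of the run-length features on the zone counts
#' `z(i, s)` with total zone count `N_z`: Short/Long Zone Emphasis, Low/High
#' Grey-Level Zone Emphasis, the joint variants, Grey-Level Non-Uniformity
#' `sum_i (sum_s z)^2 / N_z`, Size-Zone Variability
#' `sum_s (sum_i z)^2 / N_z` and Zone Percentage `N_z / N_v`.
#'
#' @param z A `sizezone_matrix`.
#' @return Named numeric vector of the eleven size-zone parameters.
#' @export
sizezone_features <- function(z) {
  stopifnot(inherits(z, "sizezone_matrix"))
  cts <- z$counts
  i <- cts$grey
  s <- cts$size
  n <- cts$n
  Nz <- z$n_zones
  by_grey <- tapply(n, i, sum)
  by_size <- tapply(n, s, sum)
  c(
    ZP = Nz / z$n_voxels,
    SZV = sum(by_size^2) / Nz,
    SZE = sum(n / s^2) / Nz,
    LZE = sum(n * s^2) / Nz,
    GLNU_Z = sum(by_grey^2) / Nz,
    LGLZE = sum(n / i^2) / Nz,
    HGLZE = sum(n * i^2) / Nz,
    SZLGLE = sum(n / (i^2 * s^2)) / Nz,
    SZHGLE = sum(n * i^2 / s^2) / Nz,
    LZLGLE = sum(n * s^2 / i^2) / Nz,
    LZHGLE = sum(n * i^2 * s^2) / Nz
  )
}

#' Intensity Variability
#'
#' Grey-level non-uniformity of the zones:
#' `IV = sum_i (sum_s z(i, s))^2 / N_z`.  Although historically listed with
#' the co-occurrence indices, it is a zone-matrix statistic and is computed
#' here from the size-zone matrix (numerically identical to `GLNU_Z`).
#'
#' @param z A `sizezone_matrix`.
#' @return The IV value (always `>= 1`... equals 1 when every zone has a
#'   distinct grey level).
#' @export
intensity_variability <- function(z) {
  unname(sizezone_features(z)[["GLNU_Z"]])
}

#' Coefficient of Variation of the raw VOI intensities
#'
#' Sample standard deviation (n - 1 denominator) of the original (never
#' resampled) in-mask voxel values divided by their mean.  Used both as the
#' 27th heterogeneity parameter and, elsewhere, as the replicate
#' reproducibility error metric.
#'
#' @param image An `image_volume`.
#' @param mask A `voi_mask` aligned with it.
#' @return The CoV (dimensionless, `>= 0`).
#' @export
coefficient_of_variation <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "voi_mask"))
  check_alignment(image, mask)
  vals <- image$data[mask$data]
  if (!length(vals)) abort("empty mask.", class = "pethet_texture_error")
  mu <- mean(vals)
  if (mu <= 0) abort("in-mask mean must be positive for CoV.", class = "pethet_texture_error")
  if (length(vals) == 1L) return(0)
  sd(vals) / mu
}

#' Compute all 27 heterogeneity parameters on a VOI
#'
#' Runs grey-level resampling, builds the three texture matrices and returns
#' the full parameter set: `CoV` plus the 26 matrix-based indices.
#'
#' @param image An `image_volume`.
#' @param mask A `voi_mask` aligned with it.
#' @param levels Number of grey levels for the resampling (default 64).
#' @return A one-row tibble with `volume_ml`, `n_voxels` and one column per
#'   parameter (see [heterogeneity_parameters()]).
#' @export
#' @examples
#' img <- image_volume(array(runif(6^3), c(6, 6, 6)), rep(2, 3))
#' voi <- spherical_voi(img, volume_ml = 0.4)
#' compute_all_features(img, voi, levels = 8)
compute_all_features <- function(image, mask, levels = 64) {
  grey <- resample_grey_levels(image, mask, levels)
  glcm <- compute_cooccurrence(grey)
  glrlm <- compute_runlength(grey)
  glszm <- compute_sizezone(grey)
  vals <- c(
    CoV = coefficient_of_variation(image, mask),
    cooccurrence_features(glcm),
    IV = intensity_variability(glszm),
    sizezone_features(glszm),
    runlength_features(glrlm)
  )
  out <- tibble(
    volume_ml = voi_volume(mask),
    n_voxels = sum(mask$data)
  )
  dplyr::bind_cols(out, as_tibble(as.list(vals[heterogeneity_parameters()])))
}
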