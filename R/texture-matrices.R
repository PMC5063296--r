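# Grey-level resampling and the three texture matrices (co-occurrence,
# run-length, size-zone), all computed strictly within the VOI: voxels
# outside the mask never contribute pairs, runs or zones.

#' Resample intensities to a fixed number of grey levels
#'
#' Fixed-bin-number discretisation of the in-mask intensities to
#' `2^S = levels` grey values:
#' `V(x) = floor(levels * (I(x) - min) / (max - min) + 1)`, clipped to
#' `levels` so the maximal voxel stays in the top bin and exactly `levels`
#' bins exist.  A constant region maps every voxel to grey 1.
#'
#' @param image An `image_volume`.
#' @param mask A `voi_mask` aligned with it.
#' @param levels Number of grey levels (default 64, i.e. S = 6).
#' @return A `grey_level_image`: integer grid (0 outside the mask), the mask,
#'   `levels`, and the original in-mask `min`/`max`.
#' @export
resample_grey_levels <- function(image, mask, levels = 64) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "voi_mask"))
  check_alignment(image, mask)
  if (!any(mask$data)) abort("empty mask.", class = "pethet_texture_error")
  stopifnot(levels >= 2)
  vals <- image$data[mask$data]
  lo <- min(vals)
  hi <- max(vals)
  g <- array(0L, dim(image$data))
  if (hi == lo) {
    g[mask$data] <- 1L
  } else {
    v <- floor(levels * (vals - lo) / (hi - lo) + 1)
    g[mask$data] <- as.integer(pmin(v, levels))
  }
  structure(
    list(
      data = g, mask = mask$data, levels = as.integer(levels),
      min = lo, max = hi, spacing = mask$spacing
    ),
    class = "grey_level_image"
  )
}

# per-offset in-mask neighbour pairs as a two-column matrix of grey values
offset_pairs <- function(grey, off) {
  d <- dim(grey$data)
  if (any(d < abs(off) + 1L)) return(cbind(integer(0), integer(0)))
  r1 <- lapply(1:3, function(k) (1L + max(0L, -off[k])):(d[k] + min(0L, -off[k])))
  r2 <- lapply(1:3, function(k) r1[[k]] + off[k])
  m1 <- grey$mask[r1[[1]], r1[[2]], r1[[3]], drop = FALSE]
  m2 <- grey$mask[r2[[1]], r2[[2]], r2[[3]], drop = FALSE]
  ok <- m1 & m2
  g1 <- grey$data[r1[[1]], r1[[2]], r1[[3]], drop = FALSE][ok]
  g2 <- grey$data[r2[[1]], r2[[2]], r2[[3]], drop = FALSE][ok]
  cbind(g1, g2)
}

#' Grey-level co-occurrence matrix averaged over 26 directions
#'
#' Symmetric pair probabilities of grey levels at nearest-neighbour voxels:
#' for each of the 26 unit offsets the in-mask pair counts are accumulated
#' symmetrically and normalised to a probability matrix, and the directional
#' matrices are averaged (directions with no valid pair are skipped).
#'
#' @param grey A `grey_level_image` from [resample_grey_levels()].
#' @return A `cooccurrence_matrix`: the averaged probability matrix `p`
#'   (`levels x levels`, sums to 1, symmetric) and the number of directions
#'   used.
#' @export
compute_cooccurrence <- function(grey) {
  stopifnot(inherits(grey, "grey_level_image"))
  L <- grey$levels
  acc <- matrix(0, L, L)
  ndir <- 0L
  for (k in seq_len(nrow(OFFSETS13))) {
    pr <- offset_pairs(grey, OFFSETS13[k, ])
    if (nrow(pr) == 0L) next
    cnt <- matrix(tabulate(pr[, 1] + (pr[, 2] - 1L) * L, L * L), L, L)
    cnt <- cnt + t(cnt) # symmetric accumulation = both offset signs
    acc <- acc + cnt / sum(cnt)
    ndir <- ndir + 1L
  }
  if (ndir == 0L) {
    abort("mask has no neighbouring voxel pairs in any direction.",
      class = "pethet_texture_error"
    )
  }
  structure(
    list(p = acc / ndir, levels = L, n_directions = 2L * ndir),
    class = "cooccurrence_matrix"
  )
}

#' Grey-level run-length matrix over 13 volumetric directions
#'
#' Maximal in-mask runs of equal grey level along each of the 13 unique 3-D
#' axis/diagonal directions, with counts aggregated over directions before
#' normalisation (the volumetric convention).
#'
#' @param grey A `grey_level_image`.
#' @param directions Matrix of direction offsets, one per row; defaults to
#'   the 13 unique volumetric directions.
#' @return A `runlength_matrix`: tibble `counts` with columns `grey`,
#'   `length`, `n`, plus `n_runs`, `n_voxels`, `n_directions`, `levels`.
#' @export
compute_runlength <- function(grey, directions = OFFSETS13) {
  stopifnot(inherits(grey, "grey_level_image"))
  directions <- rbind(directions)
  d <- dim(grey$data)
  idx <- which(grey$mask)
  if (!length(idx)) abort("empty mask.", class = "pethet_texture_error")
  pos <- arrayInd(idx, d)
  gv <- grey$data[idx]
  M <- 3 * max(d) + 2
  shift <- max(d) + 1
  run_grey <- vector("list", nrow(directions))
  run_len <- vector("list", nrow(directions))
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ]
    nz <- which(off != 0)[1]
    tt <- pos[, nz] * off[nz] # increments by one per step along the direction
    base1 <- pos[, 1] - tt * off[1] + shift
    base2 <- pos[, 2] - tt * off[2] + shift
    base3 <- pos[, 3] - tt * off[3] + shift
    key <- (base1 * M + base2) * M + base3
    o <- order(key, tt)
    kk <- key[o]
    ts <- tt[o]
    gg <- gv[o]
    n <- length(o)
    newrun <- c(
      TRUE,
      kk[-1] != kk[-n] | ts[-1] != ts[-n] + 1L | gg[-1] != gg[-n]
    )
    run_len[[k]] <- diff(c(which(newrun), n + 1L))
    run_grey[[k]] <- gg[newrun]
  }
  rg <- unlist(run_grey)
  rl <- unlist(run_len)
  counts <- dplyr::count(tibble(grey = rg, length = rl), .data$grey, .data$length)
  structure(
    list(
      counts = counts, n_runs = length(rg), n_voxels = length(idx),
      n_directions = nrow(directions), levels = grey$levels
    ),
    class = "runlength_matrix"
  )
}

#' Grey-level size-zone matrix (26-connected zones)
#'
#' Maximal 26-connected components of constant grey level within the mask,
#' counted by grey level and zone size in voxels.
#'
#' @param grey A `grey_level_image`.
#' @return A `sizezone_matrix`: tibble `counts` with columns `grey`, `size`,
#'   `n`, plus `n_zones`, `n_voxels`, `levels`.
#' @export
compute_sizezone <- function(grey) {
  stopifnot(inherits(grey, "grey_level_image"))
  idx <- which(grey$mask)
  if (!length(idx)) abort("empty mask.", class = "pethet_texture_error")
  lab <- label_components_26(grey$mask, grey = grey$data)
  memb <- lab[idx]
  size <- tabulate(memb)
  zone_grey <- integer(length(size))
  zone_grey[memb] <- grey$data[idx] # all members share the zone's grey
  counts <- dplyr::count(tibble(grey = zone_grey, size = size), .data$grey, .data$size)
  structure(
    list(
      counts = counts, n_zones = length(size), n_voxels = length(idx),
      levels = grey$levels
    ),
    class = "sizezone_matrix"
  )
}
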