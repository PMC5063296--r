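# Grid geometry, separable Gaussian filtering, trilinear resampling and
# 26-connected component labelling.  All grids are voxel-centre grids whose
# physical centre sits at the world origin; world coordinate of voxel i along
# an axis with n voxels of spacing s is (i - (n + 1)/2) * s  [mm].

axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

# world coordinates of every voxel centre, as three expanded vectors
grid_coords <- function(dim, spacing) {
  x <- axis_coords(dim[1], spacing[1])
  y <- axis_coords(dim[2], spacing[2])
  z <- axis_coords(dim[3], spacing[3])
  list(
    x = rep(x, times = dim[2] * dim[3]),
    y = rep(rep(y, each = dim[1]), times = dim[3]),
    z = rep(z, each = dim[1] * dim[2])
  )
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  w / sum(w)
}

# 1-D convolution along `axis` with zero padding at the borders
convolve_axis <- function(arr, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  if (r == 0L) return(arr * w[1])
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- d[axis]
  out <- matrix(0, n, ncol(m))
  for (j in -r:r) {
    src <- (1L + max(0L, j)):(n + min(0L, j))
    out[src - j, ] <- out[src - j, ] + w[j + r + 1L] * m[src, ]
  }
  aperm(array(out, d[perm]), order(perm))
}

# isotropic Gaussian blur specified by FWHM in mm on a possibly anisotropic grid
gaussian_blur <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  for (ax in 1:3) {
    arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_mm / spacing[ax]), ax)
  }
  arr
}

# Trilinear resampling between two centre-aligned grids; values outside the
# source grid are taken as zero.
resample_trilinear <- function(arr, spacing, out_dim, out_spacing) {
  d <- dim(arr)
  n_out <- prod(out_dim)
  # fractional source index of each target voxel centre, per axis
  fidx <- lapply(1:3, function(k) {
    axis_coords(out_dim[k], out_spacing[k]) / spacing[k] + (d[k] + 1) / 2
  })
  expand <- function(v, k) {
    switch(k,
      rep(v, times = out_dim[2] * out_dim[3]),
      rep(rep(v, each = out_dim[1]), times = out_dim[3]),
      rep(v, each = out_dim[1] * out_dim[2])
    )
  }
  f <- lapply(1:3, function(k) expand(fidx[[k]], k))
  lo <- lapply(f, floor)
  tf <- Map(`-`, f, lo)
  acc <- numeric(n_out)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ii <- lo[[1]] + a
    jj <- lo[[2]] + b
    kk <- lo[[3]] + cc
    wt <- (if (a) tf[[1]] else 1 - tf[[1]]) *
      (if (b) tf[[2]] else 1 - tf[[2]]) *
      (if (cc) tf[[3]] else 1 - tf[[3]])
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    wt[!ok] <- 0
    ii[!ok] <- 1L; jj[!ok] <- 1L; kk[!ok] <- 1L
    acc <- acc + wt * arr[ii + (jj - 1) * d[1] + (kk - 1) * d[1] * d[2]]
  }
  array(acc, out_dim)
}

# 26-connected component labelling of a logical array; when `grey` is given,
# two neighbouring voxels are connected only if they share the same grey value.
label_components_26 <- function(mask, grey = NULL) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  if (length(idx) == 1L) {
    lab[idx] <- 1L
    return(lab)
  }
  id <- integer(prod(d))
  id[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  edges <- vector("list", nrow(OFFSETS13))
  for (k in seq_len(nrow(OFFSETS13))) {
    off <- OFFSETS13[k, ]
    p1 <- pos[, 1] + off[1]
    p2 <- pos[, 2] + off[2]
    p3 <- pos[, 3] + off[3]
    ok <- p1 >= 1 & p1 <= d[1] & p2 >= 1 & p2 <= d[2] & p3 >= 1 & p3 <= d[3]
    lin2 <- p1[ok] + (p2[ok] - 1) * d[1] + (p3[ok] - 1) * d[1] * d[2]
    src <- idx[ok]
    inm <- mask[lin2]
    if (!is.null(grey)) inm <- inm & grey[src] == grey[lin2]
    if (any(inm)) edges[[k]] <- cbind(id[src[inm]], id[lin2[inm]])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}
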