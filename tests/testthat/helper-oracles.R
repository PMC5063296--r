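# Independent brute-force oracles for the texture matrices and features.
# These enumerate voxel pairs, runs and zones naively with explicit loops;
# they share no code with the package implementation.

oracle_offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

oracle_offsets13 <- oracle_offsets26[c(
  which(apply(oracle_offsets26, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  }))
), ]

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# co-occurrence: accumulate per-direction matrices over all 26 offsets,
# normalise each, average the non-empty ones
oracle_glcm <- function(grey, mask, levels) {
  d <- dim(grey)
  acc <- matrix(0, levels, levels)
  ndir <- 0
  for (k in seq_len(nrow(oracle_offsets26))) {
    off <- oracle_offsets26[k, ]
    cnt <- matrix(0, levels, levels)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      if (!mask[i, j, l]) next
      p2 <- c(i, j, l) + off
      if (!in_grid(p2, d)) next
      if (!mask[p2[1], p2[2], p2[3]]) next
      cnt[grey[i, j, l], grey[p2[1], p2[2], p2[3]]] <-
        cnt[grey[i, j, l], grey[p2[1], p2[2], p2[3]]] + 1
    }
    if (sum(cnt) > 0) {
      acc <- acc + cnt / sum(cnt)
      ndir <- ndir + 1
    }
  }
  acc / ndir
}

# run-length counts: walk every maximal line in each of the 13 directions
oracle_glrlm <- function(grey, mask, levels) {
  d <- dim(grey)
  runs <- list()
  for (k in seq_len(nrow(oracle_offsets13))) {
    off <- oracle_offsets13[k, ]
    visited <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      p <- c(i, j, l)
      if (!mask[i, j, l] || visited[i, j, l]) next
      prev <- p - off
      # only start a walk at the beginning of a maximal in-mask line
      if (in_grid(prev, d) && mask[prev[1], prev[2], prev[3]]) next
      # walk the line, splitting into runs of equal grey
      cur_g <- grey[p[1], p[2], p[3]]
      cur_len <- 0
      q <- p
      while (in_grid(q, d) && mask[q[1], q[2], q[3]]) {
        visited[q[1], q[2], q[3]] <- TRUE
        gq <- grey[q[1], q[2], q[3]]
        if (gq == cur_g) {
          cur_len <- cur_len + 1
        } else {
          runs[[length(runs) + 1]] <- c(cur_g, cur_len)
          cur_g <- gq
          cur_len <- 1
        }
        q <- q + off
      }
      runs[[length(runs) + 1]] <- c(cur_g, cur_len)
    }
  }
  m <- do.call(rbind, runs)
  out <- matrix(0, levels, max(m[, 2]))
  for (r in seq_len(nrow(m))) out[m[r, 1], m[r, 2]] <- out[m[r, 1], m[r, 2]] + 1
  out
}

# size-zone counts: BFS flood fill over 26-connected equal-grey components
oracle_glszm <- function(grey, mask, levels) {
  d <- dim(grey)
  visited <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (!mask[i, j, l] || visited[i, j, l]) next
    g0 <- grey[i, j, l]
    queue <- list(c(i, j, l))
    visited[i, j, l] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(oracle_offsets26))) {
        q <- p + oracle_offsets26[k, ]
        if (!in_grid(q, d)) next
        if (visited[q[1], q[2], q[3]] || !mask[q[1], q[2], q[3]]) next
        if (grey[q[1], q[2], q[3]] != g0) next
        visited[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(g0, size)
  }
  m <- do.call(rbind, zones)
  out <- matrix(0, levels, max(m[, 2]))
  for (r in seq_len(nrow(m))) out[m[r, 1], m[r, 2]] <- out[m[r, 1], m[r, 2]] + 1
  out
}

# features recomputed from the dense oracle matrices
oracle_glcm_features <- function(p, levels) {
  i <- row(p); j <- col(p)
  pi_m <- rowSums(p)
  mu <- sum(seq_len(levels) * pi_m)
  s2 <- sum((seq_len(levels) - mu)^2 * pi_m)
  list(
    HOM = sum(p / (1 + abs(i - j))),
    CON = sum((i - j)^2 * p),
    ENT = -sum(p[p > 0] * log2(p[p > 0])),
    COR = if (s2 < 1e-12) 0 else (sum(i * j * p) - mu^2) / s2
  )
}

oracle_rl_features <- function(r, n_vox, n_dir) {
  i <- row(r); l <- col(r)
  Nr <- sum(r)
  list(
    RP = Nr / (n_vox * n_dir),
    SRE = sum(r / l^2) / Nr, LRE = sum(r * l^2) / Nr,
    GLNU_R = sum(rowSums(r)^2) / Nr,
    LGLRE = sum(r / i^2) / Nr, HGLRE = sum(r * i^2) / Nr,
    SRLGLE = sum(r / (i^2 * l^2)) / Nr, SRHGLE = sum(r * i^2 / l^2) / Nr,
    LRLGLE = sum(r * l^2 / i^2) / Nr, LRHGLE = sum(r * i^2 * l^2) / Nr
  )
}

oracle_sz_features <- function(z, n_vox) {
  i <- row(z); s <- col(z)
  Nz <- sum(z)
  list(
    ZP = Nz / n_vox,
    SZV = sum(colSums(z)^2) / Nz, GLNU_Z = sum(rowSums(z)^2) / Nz,
    SZE = sum(z / s^2) / Nz, LZE = sum(z * s^2) / Nz,
    LGLZE = sum(z / i^2) / Nz, HGLZE = sum(z * i^2) / Nz,
    SZLGLE = sum(z / (i^2 * s^2)) / Nz, SZHGLE = sum(z * i^2 / s^2) / Nz,
    LZLGLE = sum(z * s^2 / i^2) / Nz, LZHGLE = sum(z * i^2 * s^2) / Nz
  )
}
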