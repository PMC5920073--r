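# Independent oracles used across the suite. These deliberately share no
# code with the package: flood fill is a plain R breadth-first search,
# Otsu is an explicit loop over cut points, and distances/spheres are
# enumerated voxel by voxel.

# first-encounter raster-order connected components by BFS
flood_fill_labels <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  m <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[m <= switch(as.character(connectivity),
                           "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, dims)
  nxt <- 0L
  # iterate in linear (z fastest) order: (z, y, x) raster
  for (i in seq_len(prod(dims))) {
    if (!mask[i] || lab[i] != 0) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(nb < 1) || any(nb > dims)) next
        j <- nb[1] + dims[1] * ((nb[2] - 1) + dims[2] * (nb[3] - 1))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# exhaustive Otsu: recompute class weights and means from scratch for every
# cut point, return the level (upper edge of the background bin)
brute_otsu <- function(v, n_bins = 256) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best_k <- NA
  best_var <- -Inf
  for (k in seq_len(n_bins - 1)) {
    in0 <- bin <= k
    n0 <- sum(in0)
    n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[in0]])
    mu1 <- mean(mids[bin[!in0]])
    bcv <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (bcv > best_var + 1e-12) {
      best_var <- bcv
      best_k <- k
    }
  }
  breaks[best_k + 1]
}

# all-pairs squared distance to the nearest feature voxel (tiny grids only)
brute_edt_sq <- function(feature, spacing) {
  dims <- dim(feature)
  fidx <- which(feature)
  fco <- sweep(arrayInd(fidx, dims), 2, spacing, `*`)
  out <- array(Inf, dims)
  for (i in seq_len(prod(dims))) {
    co <- arrayInd(i, dims) * spacing
    out[i] <- min(colSums((t(fco) - as.numeric(co))^2))
  }
  out
}

# direct center-in-sphere voxelization over the full grid
brute_sphere_mask <- function(center, r, spacing, dims) {
  g <- expand.grid(z = (seq_len(dims[1]) - 0.5) * spacing[1],
                   y = (seq_len(dims[2]) - 0.5) * spacing[2],
                   x = (seq_len(dims[3]) - 0.5) * spacing[3])
  d2 <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2
  array(d2 <= r^2, dims)
}

# small labeled sphere pair used by splitting tests: two equal spheres with
# centers `gap_vox` voxels apart along x, unit calibration
two_sphere_mask <- function(r = 4, gap_vox = 2 * 4, dims = c(11, 11, 21)) {
  c1 <- c(dims[1] / 2, dims[2] / 2, dims[3] / 2 - gap_vox / 2)
  c2 <- c(dims[1] / 2, dims[2] / 2, dims[3] / 2 + gap_vox / 2)
  m1 <- brute_sphere_mask(c1, r, c(1, 1, 1), dims)
  m2 <- brute_sphere_mask(c2, r, c(1, 1, 1), dims)
  list(mask = m1 | m2, m1 = m1, m2 = m2)
}

unit_cal <- function() calibration(1, 1, 1)

# tiny deterministic label volume builders
lv <- function(arr, cal = unit_cal(), kind = "droplet")
  label_volume(arr, cal, kind)
is_stack <- function(arr, cal = unit_cal(), channel = "fluorescence")
  intensity_stack(arr, cal, channel)
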