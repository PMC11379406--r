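# Independent brute-force oracles used across the suite.  These never call
# the package's distance/metric code paths: distances are all-pairs physical
# distances, statistics are explicit summation loops.

# physical voxel-center coordinates of every TRUE voxel
mask_coords <- function(m, spacing) {
  idx <- which(m, arr.ind = TRUE)
  sweep(idx - 0.5, 2, spacing, "*")
}

# all-pairs Euclidean distance transform; chunked so grids up to ~40^3 fit
brute_edt <- function(m, spacing) {
  dims <- dim(m)
  inside <- mask_coords(m, spacing)
  outside <- mask_coords(!m, spacing)
  min_dist_to <- function(pts, targets) {
    out <- numeric(nrow(pts))
    chunk <- 200L
    for (s in seq(1, nrow(pts), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(pts))
      blk <- pts[s:e, , drop = FALSE]
      d2 <- outer(rowSums(blk^2), rowSums(targets^2), "+") -
        2 * blk %*% t(targets)
      out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    out
  }
  d_in <- array(0, dim = dims)
  d_out <- array(0, dim = dims)
  if (nrow(inside) > 0 && nrow(outside) > 0) {
    d_in[m] <- min_dist_to(inside, outside)
    d_out[!m] <- min_dist_to(outside, inside)
  }
  list(d_in = d_in, d_out = d_out)
}

# one step of binary erosion with the Euclidean unit-ball structuring
# element (face neighbors at 1 mm isotropic); out-of-grid is background
brute_erode <- function(m) {
  dims <- dim(m)
  out <- m
  pad <- array(FALSE, dim = dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- m
  iz <- 2:(dims[1] + 1); iy <- 2:(dims[2] + 1); ix <- 2:(dims[3] + 1)
  keep <- pad[iz, iy, ix] &
    pad[iz - 1, iy, ix] & pad[iz + 1, iy, ix] &
    pad[iz, iy - 1, ix] & pad[iz, iy + 1, ix] &
    pad[iz, iy, ix - 1] & pad[iz, iy, ix + 1]
  array(keep, dim = dims)
}

# solid cube mask fixture: side s centered in an n^3 grid
cube_mask <- function(n = 11L, side = 7L, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dim = rep(n, 3))
  lo <- (n - side) %/% 2 + 1L
  hi <- lo + side - 1L
  m[lo:hi, lo:hi, lo:hi] <- TRUE
  label_mask(m, spacing, "cube")
}

# random connected-ish blob: union of a few balls, kept away from the edge
random_blob_mask <- function(dims = c(12L, 12L, 12L), n_balls = 3L,
                             spacing = c(1, 1, 1)) {
  cc <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  m <- array(FALSE, dim = dims)
  for (b in seq_len(n_balls)) {
    cen <- runif(3, 0.3, 0.7) * dims * spacing
    r <- runif(1, 1.2, 0.22 * min(dims * spacing))
    q <- outer(outer((cc[[1]] - cen[1])^2, (cc[[2]] - cen[2])^2, "+"),
               (cc[[3]] - cen[3])^2, "+")
    m <- m | (q <= r^2)
  }
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                 ceiling(dims[3] / 2)] <- TRUE
  label_mask(m, spacing, "blob")
}

# population mean/sd by explicit loop
brute_stats <- function(vol, mask) {
  idx <- which(mask$data)
  s <- 0
  for (i in idx) s <- s + vol$data[i]
  mu <- s / length(idx)
  ss <- 0
  for (i in idx) ss <- ss + (vol$data[i] - mu)^2
  list(mean = mu, sd = sqrt(ss / length(idx)), n = length(idx))
}

# Pearson correlation by explicit arithmetic
brute_cc <- function(vol_A, vol_B, mask) {
  a <- vol_A$data[mask$data]
  b <- vol_B$data[mask$data]
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  cov_ab <- sum((a - ma) * (b - mb)) / length(a)
  cov_ab / (sqrt(sum((a - ma)^2) / length(a)) *
              sqrt(sum((b - mb)^2) / length(b)))
}

# a small, quick phantom for tests that only need structure, not scale;
# the tumor sits clear of the mid-plane so its mirror image is separated
# from the peritumoral halo, and the ventricle stays out of both regions
small_phantom_spec <- function(..., seed = 7L) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
               brain_center = c(16, 16, 16), brain_semiaxes = c(13, 14, 13),
               tumor_center = c(16, 16, 23), tumor_semiaxes = c(4, 4, 4),
               ventricle_segments = list(
                 list(p1 = c(14, 10, 15), p2 = c(14, 22, 15), radius = 1)),
               seed = seed, ...)
}
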