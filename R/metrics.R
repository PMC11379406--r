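#' Mean, standard deviation and voxel count over a region
#'
#' The shared primitive behind every contrast metric.  The standard
#' deviation is the population form (divide by n): a mask is an
#' exhaustive voxel set, not a sample.
#'
#' @param vol a [volume3d()].
#' @param mask a non-empty [label_mask()] co-registered with `vol`.
#' @return An object of class `region_stats`: `mean`, `sd`, `n_voxels`,
#'   `region_name`.
#' @export
region_stats <- function(vol, mask) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "label_mask"))
  assert_coregistered(list(volume = vol, mask = mask))
  n <- sum(mask$data)
  if (n == 0L)
    stop("region_stats: mask is empty", call. = FALSE)
  v <- vol$data[mask$data]
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  structure(list(mean = mu, sd = sdev, n_voxels = n,
                 region_name = mask$name),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("<region_stats '%s'> mean %.6g, sd %.6g, n %d\n",
              x$region_name, x$mean, x$sd, x$n_voxels))
  invisible(x)
}

#' Whole-tumor tumor-to-background ratio
#'
#' Ratio of mean fluorescence in the whole tumor region to the mean in
#' an equivalently sized normal-tissue reference (conventionally the
#' mirrored contralateral volume).
#'
#' @param vol a [volume3d()].
#' @param tumor tumor [label_mask()].
#' @param reference normal-tissue reference [label_mask()].
#' @return Scalar TBR.
#' @export
tbr_whole <- function(vol, tumor, reference) {
  mt <- region_stats(vol, tumor)$mean
  mr <- region_stats(vol, reference)$mean
  if (mr <= 0)
    stop("tbr_whole: reference mean is <= 0; ratio undefined for non-positive background",
         call. = FALSE)
  mt / mr
}

#' Margin tumor-to-background ratio
#'
#' Ratio of mean fluorescence in the outermost 1 mm of the tumor to the
#' adjacent 1 mm peritumoral rind — the contrast a surgeon actually sees
#' at the resection margin.
#'
#' @param vol a [volume3d()].
#' @param inner_1mm first inward shell [label_mask()].
#' @param outer_1mm first outward shell [label_mask()].
#' @return Scalar TBR.
#' @export
tbr_margin <- function(vol, inner_1mm, outer_1mm) {
  mi <- region_stats(vol, inner_1mm)$mean
  mo <- region_stats(vol, outer_1mm)$mean
  if (mo <= 0)
    stop("tbr_margin: outer margin mean is <= 0; ratio undefined",
         call. = FALSE)
  mi / mo
}

#' Contrast-to-noise ratio
#'
#' `(mean(signal) - mean(noise)) / sd(noise)` with population sd.  For
#' the whole-tumor variant the noise region is the contralateral
#' reference; for the margin variant it is the 1 mm peritumoral rind.
#'
#' @param vol a [volume3d()].
#' @param signal_region [label_mask()] of the signal region.
#' @param noise_region [label_mask()] of the reference region; must not
#'   be constant.
#' @return Scalar CNR.
#' @export
cnr <- function(vol, signal_region, noise_region) {
  s <- region_stats(vol, signal_region)
  n <- region_stats(vol, noise_region)
  if (n$sd <= 0)
    stop("cnr: noise region is constant (sd = 0); CNR undefined",
         call. = FALSE)
  (s$mean - n$mean) / n$sd
}

new_profile_curve <- function(positions, values, channel, kind) {
  mx <- max(values)
  if (mx > 0) values <- values / mx
  structure(list(positions = positions, values = values,
                 channel = channel, kind = kind),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve %s '%s'> %d points, positions [%.3g, %.3g] mm\n",
              x$kind, x$channel, length(x$values),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Distance-resolved shell intensity profile
#'
#' Mean intensity per concentric shell, normalized to the highest-
#' intensity shell (max value 1).  Positions are shell mid-distances
#' `(k - 0.5) * thickness`, signed negative for inward shells and
#' positive for outward shells, so a combined inward+outward profile
#' reads left-to-right from tumor depth into normal tissue.  Pass a
#' single decomposition or a list (e.g. `list(inward, outward)`) to
#' concatenate; points are returned sorted by position and normalized
#' over the combined curve.
#'
#' @param vol a [volume3d()].
#' @param shells a `shell_decomposition` or list of them.
#' @param channel label stored on the curve.
#' @return A `profile_curve` with `kind = "shell"`.
#' @export
shell_profile <- function(vol, shells, channel = "") {
  if (inherits(shells, "shell_decomposition")) shells <- list(shells)
  stopifnot(length(shells) > 0L,
            all(vapply(shells, inherits, logical(1), "shell_decomposition")))
  pos <- numeric(0)
  val <- numeric(0)
  for (dec in shells) {
    if (length(dec$shells) == 0L) next
    sgn <- if (dec$direction == "inward") -1 else 1
    for (k in seq_along(dec$shells)) {
      pos <- c(pos, sgn * (k - 0.5) * dec$thickness_mm)
      val <- c(val, region_stats(vol, dec$shells[[k]])$mean)
    }
  }
  if (length(val) == 0L)
    stop("shell_profile: decomposition has no shells", call. = FALSE)
  ord <- order(pos)
  new_profile_curve(pos[ord], val[ord], channel, "shell")
}

#' Line intensity profile through the volume
#'
#' Samples the volume by trilinear interpolation at `n_samples` equally
#' spaced points between two physical endpoints (mm, `(z, y, x)` order,
#' with voxel i centered at `(i - 0.5) * spacing`), then normalizes the
#' curve to max 1.  Endpoints must lie within the span of voxel centers
#' so interpolation never extrapolates.
#'
#' @param vol a [volume3d()].
#' @param start_mm,end_mm physical endpoints, length-3 mm `(z, y, x)`.
#' @param n_samples number of samples (>= 2).
#' @param channel label stored on the curve.
#' @return A `profile_curve` with `kind = "line"`; positions are mm from
#'   `start_mm`.
#' @export
line_profile <- function(vol, start_mm, end_mm, n_samples = 100L,
                         channel = "") {
  stopifnot(inherits(vol, "volume3d"), n_samples >= 2L)
  start_mm <- as.numeric(start_mm); end_mm <- as.numeric(end_mm)
  stopifnot(length(start_mm) == 3L, length(end_mm) == 3L)
  dims <- dim(vol$data)
  lo <- 0.5 * vol$spacing
  hi <- (dims - 0.5) * vol$spacing
  for (p in list(start_mm, end_mm))
    if (any(p < lo - 1e-9) || any(p > hi + 1e-9))
      stop(sprintf(
        "line_profile: endpoint (%.3g, %.3g, %.3g) mm is outside the interpolable grid [voxel centers span (%.3g..%.3g, %.3g..%.3g, %.3g..%.3g) mm]",
        p[1], p[2], p[3], lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]),
        call. = FALSE)
  t <- seq(0, 1, length.out = n_samples)
  vals <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    p <- start_mm + t[i] * (end_mm - start_mm)
    # continuous voxel coordinate: voxel i center at (i - 0.5) * spacing
    g <- p / vol$spacing + 0.5
    g0 <- pmin(pmax(floor(g), 1), dims - 1)
    f <- g - g0
    f <- pmin(pmax(f, 0), 1)
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dz) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dx) f[3] else 1 - f[3])
      acc <- acc + w * vol$data[g0[1] + dz, g0[2] + dy, g0[3] + dx]
    }
    vals[i] <- acc
  }
  dist_mm <- sqrt(sum((end_mm - start_mm)^2))
  new_profile_curve(t * dist_mm, vals, channel, "line")
}

#' Bivariate joint histogram of two channels within a region
#'
#' Each channel is min-max normalized to \[0, 1\] within the region,
#' then paired values are counted on a uniform `n_bins` x `n_bins` grid
#' (default 100 bins per axis).  The last bin is right-closed so the
#' maximum value is counted and total counts equal the region size.
#'
#' @param vol_A,vol_B co-registered [volume3d()] channels.
#' @param mask a non-empty [label_mask()].
#' @param n_bins bins per axis (default 100).
#' @return An object of class `joint_histogram`: `counts`
#'   (`n_bins x n_bins`, rows = A bins, columns = B bins), `edges_A`,
#'   `edges_B` (length `n_bins + 1` on \[0, 1\]), `norm_params_A`,
#'   `norm_params_B` ((min, max) used), `region_name`.
#' @export
joint_histogram <- function(vol_A, vol_B, mask, n_bins = 100L) {
  stopifnot(inherits(vol_A, "volume3d"), inherits(vol_B, "volume3d"),
            inherits(mask, "label_mask"))
  assert_coregistered(list(A = vol_A, B = vol_B, mask = mask))
  if (n_bins < 1L)
    stop("joint_histogram: n_bins must be >= 1", call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("joint_histogram: mask is empty", call. = FALSE)
  a <- vol_A$data[mask$data]
  b <- vol_B$data[mask$data]
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("joint_histogram: a channel is constant within the region; min-max normalization undefined",
         call. = FALSE)
  an <- (a - ra[1]) / (ra[2] - ra[1])
  bn <- (b - rb[1]) / (rb[2] - rb[1])
  ia <- pmin(floor(an * n_bins) + 1L, n_bins)   # right-closed last bin
  ib <- pmin(floor(bn * n_bins) + 1L, n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ia, levels = seq_len(n_bins)),
               factor(ib, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  structure(list(counts = counts, edges_A = edges, edges_B = edges,
                 norm_params_A = ra, norm_params_B = rb,
                 n_bins = as.integer(n_bins), region_name = mask$name),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram '%s'> %d x %d bins, %d voxels\n",
              x$region_name, x$n_bins, x$n_bins, sum(x$counts)))
  invisible(x)
}

#' Marginal counts of a joint histogram
#'
#' @param jh a [joint_histogram()].
#' @param channel `"A"` or `"B"`.
#' @return Integer vector of per-bin counts of the requested channel.
#' @export
histogram_marginal <- function(jh, channel = c("A", "B")) {
  channel <- match.arg(channel)
  if (channel == "A") rowSums(jh$counts) else colSums(jh$counts)
}

#' Slice a joint histogram at a fixed normalized-value band
#'
#' Returns the frequency of the other channel's normalized values for
#' voxels whose fixed channel falls in `bin_range` — e.g. the frequency
#' of normalized channel-B values among voxels with normalized channel-A
#' values between 0.40 and 0.42.  `bin_range` must align with bin edges.
#'
#' @param jh a [joint_histogram()].
#' @param channel the channel held fixed, `"A"` or `"B"`.
#' @param bin_range length-2 normalized range aligned with bin edges.
#' @return Integer frequency vector over the other channel's bins.
#' @export
slice_histogram <- function(jh, channel = c("A", "B"), bin_range) {
  channel <- match.arg(channel)
  stopifnot(inherits(jh, "joint_histogram"), length(bin_range) == 2L)
  edges <- if (channel == "A") jh$edges_A else jh$edges_B
  tol <- 1e-9
  i_lo <- which(abs(edges - bin_range[1]) < tol)
  i_hi <- which(abs(edges - bin_range[2]) < tol)
  if (length(i_lo) != 1L || length(i_hi) != 1L || i_hi <= i_lo) {
    near <- function(x) edges[which.min(abs(edges - x))]
    stop(sprintf(
      "slice_histogram: range [%.4g, %.4g] does not align with bin edges; nearest valid edges are %.4g and %.4g",
      bin_range[1], bin_range[2], near(bin_range[1]), near(bin_range[2])),
      call. = FALSE)
  }
  bins <- seq.int(i_lo, i_hi - 1L)
  if (channel == "A") {
    as.integer(colSums(jh$counts[bins, , drop = FALSE]))
  } else {
    as.integer(rowSums(jh$counts[, bins, drop = FALSE]))
  }
}

#' Region-restricted normalized cross-correlation of two channels
#'
#' Covariance of the two channels over the masked voxels divided by the
#' product of their standard deviations (the Pearson correlation of the
#' paired voxel intensities).  Invariant under positive affine
#' rescaling of either channel, so raw and normalized intensities give
#' the same value.
#'
#' @param vol_A,vol_B co-registered [volume3d()] channels.
#' @param mask a non-empty [label_mask()]; both channels must be
#'   non-constant within it.
#' @return Scalar in \[-1, 1\].
#' @export
cross_correlation <- function(vol_A, vol_B, mask) {
  stopifnot(inherits(vol_A, "volume3d"), inherits(vol_B, "volume3d"),
            inherits(mask, "label_mask"))
  assert_coregistered(list(A = vol_A, B = vol_B, mask = mask))
  if (sum(mask$data) == 0L)
    stop("cross_correlation: mask is empty", call. = FALSE)
  a <- vol_A$data[mask$data]
  b <- vol_B$data[mask$data]
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean((a - ma)^2))
  sb <- sqrt(mean((b - mb)^2))
  if (sa <= 0 || sb <= 0)
    stop("cross_correlation: a channel is constant within the region; correlation undefined",
         call. = FALSE)
  cc <- mean((a - ma) * (b - mb)) / (sa * sb)
  min(max(cc, -1), 1)
}
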