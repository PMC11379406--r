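vol_of <- function(arr, spacing = c(1, 1, 1)) volume3d(arr, spacing)

mask_at <- function(dims, idx, spacing = c(1, 1, 1), name = "r") {
  m <- array(FALSE, dim = dims)
  m[idx] <- TRUE
  label_mask(m, spacing, name)
}

test_that("region statistics use the population convention", {
  a <- array(5, dim = c(3, 3, 3))
  v <- vol_of(a)
  s <- region_stats(v, mask_at(c(3, 3, 3), 1:5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$n_voxels, 5)

  a2 <- array(0, dim = c(2, 2, 2)); a2[1] <- 2; a2[2] <- 4
  s2 <- region_stats(vol_of(a2), mask_at(c(2, 2, 2), 1:2))
  expect_equal(s2$mean, 3)
  expect_equal(s2$sd, 1)   # population sd of {2, 4}

  withr::with_seed(5, {
    arr <- array(runif(1000) * 100, dim = c(10, 10, 10))
    v3 <- vol_of(arr)
    mk <- mask_at(c(10, 10, 10), sample(1000, 300))
    s3 <- region_stats(v3, mk)
    o <- brute_stats(v3, mk)
    expect_equal(s3$mean, o$mean, tolerance = 1e-13)
    expect_equal(s3$sd, o$sd, tolerance = 1e-13)
  })

  expect_error(region_stats(v, mask_at(c(3, 3, 3), integer(0))), "empty")
})

test_that("TBR variants behave as ratios of region means", {
  dims <- c(4, 4, 4)
  arr <- array(2, dim = dims)
  arr[1:8] <- 10
  v <- vol_of(arr)
  tum <- mask_at(dims, 1:8, name = "tumor")
  ref <- mask_at(dims, 33:40, name = "ref")
  expect_equal(tbr_whole(v, tum, ref), 5.0)
  expect_equal(tbr_whole(v, tum, tum), 1.0)

  arr2 <- array(0, dim = dims); arr2[1:4] <- 4; arr2[5:8] <- 2
  v2 <- vol_of(arr2)
  expect_equal(tbr_margin(v2, mask_at(dims, 1:4), mask_at(dims, 5:8)), 2.0)
  expect_equal(tbr_margin(v2, mask_at(dims, 1:4), mask_at(dims, 1:4)), 1.0)

  expect_error(tbr_whole(v2, tum, mask_at(dims, 33:40)), "<= 0")
})

test_that("CNR is the mean difference scaled by the reference sd", {
  dims <- c(4, 4, 4)
  arr <- array(0, dim = dims)
  arr[1:8] <- 10
  arr[33:40] <- c(1, 3, 1, 3, 1, 3, 1, 3)  # mean 2, population sd 1
  v <- vol_of(arr)
  sig <- mask_at(dims, 1:8); noi <- mask_at(dims, 33:40)
  expect_equal(cnr(v, sig, noi), 8.0)
  expect_equal(cnr(v, noi, noi), 0.0)
  expect_error(cnr(v, sig, mask_at(dims, 41:48)), "constant")
})

test_that("CNR estimates track analytic truth on Gaussian phantoms", {
  # short peritumoral decay keeps the mirrored reference region flat, so
  # its measured sd is the noise sd alone
  spec0 <- small_phantom_spec(background_level = c(A = 500, B = 500),
                              rim_peak = 1000, core_peak = 1200,
                              peritumoral_decay_mm = 1,
                              noise_sd = c(A = 0, B = 0))
  mu <- analytic_region_means(spec0, "tumor")[["A"]]
  mun <- analytic_region_means(spec0, "contralateral")[["A"]]
  sd_target <- (mu - mun) / 8      # analytic CNR of 8
  vals <- sapply(1:12, function(s) {
    spec <- small_phantom_spec(background_level = c(A = 500, B = 500),
                               rim_peak = 1000, core_peak = 1200,
                               peritumoral_decay_mm = 1,
                               noise_sd = c(A = sd_target, B = 0),
                               seed = 1000L + s)
    ph <- generate_phantom(spec)
    pl <- phantom_symmetry_plane(spec)
    contra <- contralateral_region(ph$tumor, pl$axis, pl$coordinate)
    cnr(ph$channel_A, ph$tumor, contra)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 8), 3 * se + 1e-9)
})

test_that("shell profiles are max-normalized and ordered by signed distance", {
  mk <- cube_mask(13L, 7L)
  const <- vol_of(array(4, dim = c(13, 13, 13)))
  dec <- inward_shells(mk)
  p <- shell_profile(const, dec)
  expect_true(all(p$values == 1))
  expect_equal(p$positions, c(-3.5, -2.5, -1.5, -0.5))
  expect_true(all(diff(p$positions) > 0))

  # combined inward+outward: positions signed, means match brute loops
  withr::with_seed(17, {
    arr <- array(runif(13^3) * 10, dim = c(13, 13, 13))
    v <- vol_of(arr)
    outd <- outward_shells(mk, n_shells = 2)
    pc <- shell_profile(v, list(dec, outd))
    expect_equal(pc$positions, c(-3.5, -2.5, -1.5, -0.5, 0.5, 1.5))
    all_shells <- c(rev(dec$shells), outd$shells)
    means <- vapply(all_shells, function(s) brute_stats(v, s)$mean,
                    numeric(1))
    expect_equal(pc$values, means / max(means), tolerance = 1e-13)
    expect_equal(max(pc$values), 1)
  })
})

test_that("rim and core phantoms peak in opposite shells", {
  spec <- small_phantom_spec(noise_sd = c(A = 0, B = 0))
  ph <- generate_phantom(spec)
  dec <- inward_shells(ph$tumor)
  pA <- shell_profile(ph$channel_A, dec, channel = "A")
  pB <- shell_profile(ph$channel_B, dec, channel = "B")
  # inward positions ascend toward the boundary (position -0.5 is outermost)
  expect_equal(which.max(pA$values), length(pA$values))  # outermost shell
  expect_equal(which.max(pB$values), 1L)                 # innermost shell
  # core channel rises strictly with depth
  expect_true(all(diff(pB$values) < 0))
})

test_that("line profiles interpolate trilinearly and normalize to 1", {
  const <- vol_of(array(7, dim = c(5, 5, 5)))
  p <- line_profile(const, c(1, 1, 1), c(4, 4, 4), n_samples = 10)
  expect_equal(p$values, rep(1, 10), tolerance = 1e-14)
  expect_equal(max(p$positions), sqrt(27), tolerance = 1e-12)

  # affine field is reproduced exactly by trilinear interpolation
  cc <- (1:5) - 0.5
  aff <- outer(outer(2 * cc, 3 * cc, "+"), 5 * cc, "+") + 1
  va <- vol_of(array(aff, dim = c(5, 5, 5)))
  pa <- line_profile(va, c(0.7, 1.1, 0.9), c(4.2, 3.8, 4.4),
                     n_samples = 7)
  t <- seq(0, 1, length.out = 7)
  pts <- cbind(0.7 + t * 3.5, 1.1 + t * 2.7, 0.9 + t * 3.5)
  truth <- 2 * pts[, 1] + 3 * pts[, 2] + 5 * pts[, 3] + 1
  expect_equal(pa$values, truth / max(truth), tolerance = 1e-12)

  # hand-computed trilinear value on a 3^3 volume: midpoint of the cell
  # spanned by voxels (1..2)^3 averages all eight corners
  arr <- array(as.double(1:27), dim = c(3, 3, 3))
  vh <- vol_of(arr)
  # diagonal from the center of voxel (1,1,1) to the center of (2,2,2);
  # the midpoint averages the eight cell corners: (1+2+4+5+10+11+13+14)/8
  ph <- line_profile(vh, c(0.5, 0.5, 0.5), c(1.5, 1.5, 1.5), n_samples = 3)
  expected_mid <- 7.5
  raw <- c(arr[1, 1, 1], expected_mid, arr[2, 2, 2])
  expect_equal(ph$values, raw / max(raw), tolerance = 1e-12)

  expect_error(line_profile(const, c(0.1, 1, 1), c(4, 4, 4)), "outside")
})

test_that("joint histograms conserve counts and match 1-D marginal oracles", {
  dims <- c(8, 8, 8)
  withr::with_seed(29, {
    a <- array(runif(512) * 50 + 5, dim = dims)
    b <- array(runif(512) * 9 + 1, dim = dims)
    vA <- vol_of(a); vB <- vol_of(b)
    mk <- mask_at(dims, sample(512, 200), name = "tumor")
    jh <- joint_histogram(vA, vB, mk, n_bins = 100)
    expect_equal(sum(jh$counts), 200)
    expect_equal(dim(jh$counts), c(100, 100))

    # marginals vs independent 1-D binning
    av <- a[mk$data]; bv <- b[mk$data]
    an <- (av - min(av)) / (max(av) - min(av))
    bn <- (bv - min(bv)) / (max(bv) - min(bv))
    bin1d <- function(x) tabulate(pmin(floor(x * 100) + 1L, 100L), 100L)
    expect_equal(unname(histogram_marginal(jh, "A")), bin1d(an))
    expect_equal(unname(histogram_marginal(jh, "B")), bin1d(bn))
  })

  # extreme-value voxels land in the first and last (right-closed) bins
  a2 <- array(0, dim = c(2, 2, 2)); a2[1] <- 1; a2[2] <- 9
  b2 <- array(0, dim = c(2, 2, 2)); b2[1] <- 2; b2[2] <- 4
  jh2 <- joint_histogram(vol_of(a2), vol_of(b2), mask_at(c(2, 2, 2), 1:2))
  expect_equal(jh2$counts[1, 1], 1L)
  expect_equal(jh2$counts[100, 100], 1L)
  expect_equal(sum(jh2$counts), 2L)

  expect_error(joint_histogram(vol_of(array(3, dim = c(2, 2, 2))),
                               vol_of(b2), mask_at(c(2, 2, 2), 1:2)),
               "constant")
})

test_that("histogram slices select aligned normalized-value bands", {
  dims <- c(8, 8, 8)
  withr::with_seed(37, {
    a <- array(runif(512), dim = dims)
    b <- array(runif(512), dim = dims)
    vA <- vol_of(a); vB <- vol_of(b)
    mk <- mask_at(dims, 1:512)
    jh <- joint_histogram(vA, vB, mk, n_bins = 100)

    # summing the slice over the full range recovers the total count
    expect_equal(sum(slice_histogram(jh, "A", c(0, 1))), 512L)

    # the canonical 0.40-0.42 band vs a direct filter-and-bin oracle
    sl <- slice_histogram(jh, "A", c(0.40, 0.42))
    av <- a[mk$data]; bv <- b[mk$data]
    an <- (av - min(av)) / (max(av) - min(av))
    bn <- (bv - min(bv)) / (max(bv) - min(bv))
    ia <- pmin(floor(an * 100) + 1L, 100L)
    keep <- ia %in% c(41L, 42L)
    oracle <- tabulate(pmin(floor(bn[keep] * 100) + 1L, 100L), 100L)
    expect_equal(sl, oracle)
    expect_equal(sum(sl), sum(keep))
  })

  # single-voxel histogram: the slice holds a single 1
  a1 <- array(0, dim = c(2, 2, 2)); a1[1] <- 0.3; a1[2] <- 0.9
  b1 <- array(0, dim = c(2, 2, 2)); b1[1] <- 0.2; b1[2] <- 0.6
  jh1 <- joint_histogram(vol_of(a1), vol_of(b1), mask_at(c(2, 2, 2), 1:2))
  sl1 <- slice_histogram(jh1, "A", c(0, 0.01))   # first A bin: the min voxel
  expect_equal(sum(sl1), 1L)
  expect_equal(sl1[1], 1L)                        # B is at its min there

  expect_error(slice_histogram(jh1, "A", c(0.401, 0.42)), "nearest valid")
})

test_that("cross-correlation is Pearson over the region and affine-invariant", {
  dims <- c(4, 4, 4)
  withr::with_seed(41, {
    a <- array(runif(64), dim = dims)
    vA <- vol_of(a)
    mk <- mask_at(dims, 1:64)
    expect_equal(cross_correlation(vA, vA, mk), 1.0)
    vNeg <- vol_of(10 - a)
    expect_equal(cross_correlation(vA, vNeg, mk), -1.0)

    b <- array(runif(64), dim = dims)
    vB <- vol_of(b)
    cc0 <- cross_correlation(vA, vB, mk)
    expect_equal(cc0, brute_cc(vA, vB, mk), tolerance = 1e-13)
    expect_equal(cc0, cor(a[mk$data], b[mk$data]), tolerance = 1e-12)

    # invariance under positive affine rescaling of either channel
    vA2 <- vol_of(3.7 * a + 11)
    vB2 <- vol_of(0.02 * b + 5)
    expect_equal(cross_correlation(vA2, vB2, mk), cc0, tolerance = 1e-10)
  })

  # small hand-built region
  a4 <- array(0, dim = c(2, 2, 1)); a4[] <- c(1, 2, 3, 4)
  b4 <- array(0, dim = c(2, 2, 1)); b4[] <- c(2, 1, 4, 3)
  mk4 <- label_mask(array(TRUE, dim = c(2, 2, 1)), c(1, 1, 1))
  # by hand: cov = 0.75, sd_a = sd_b = sqrt(1.25) -> cc = 0.75/1.25 = 0.6
  expect_equal(cross_correlation(vol_of(a4), vol_of(b4), mk4), 0.6,
               tolerance = 1e-12)

  expect_error(cross_correlation(vol_of(array(2, dim = dims)),
                                 vol_of(array(runif(64), dim = dims)),
                                 mask_at(dims, 1:64)),
               "constant")
})
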