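test_that("boundary distances match all-pairs brute force", {
  # single voxel, 1 mm isotropic: distance to the adjacent background center
  m1 <- array(FALSE, dim = c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  mk1 <- label_mask(m1, c(1, 1, 1))
  bd1 <- boundary_distance(mk1)
  expect_equal(bd1$d_in[3, 3, 3], 1.0)
  expect_true(all(bd1$d_in[!m1] == 0))

  # 7^3 cube: center voxel is 4 mm from the nearest background center
  mk <- cube_mask(11L, 7L)
  bd <- boundary_distance(mk)
  expect_equal(bd$d_in[6, 6, 6], 4.0)
  oracle <- brute_edt(mk$data, mk$spacing)
  expect_equal(bd$d_in, oracle$d_in, tolerance = 1e-12)
  expect_equal(bd$d_out, oracle$d_out, tolerance = 1e-12)

  # anisotropic spacing: a z step counts 2 mm
  mka <- cube_mask(9L, 5L, spacing = c(2, 1, 1))
  bda <- boundary_distance(mka)
  oa <- brute_edt(mka$data, mka$spacing)
  expect_equal(bda$d_in, oa$d_in, tolerance = 1e-12)
  expect_equal(bda$d_out, oa$d_out, tolerance = 1e-12)

  # random blobs
  withr::with_seed(11, {
    for (rep in 1:5) {
      mk <- random_blob_mask(c(10L, 11L, 9L), spacing = c(1, 1.5, 0.75))
      bd <- boundary_distance(mk)
      o <- brute_edt(mk$data, mk$spacing)
      expect_equal(bd$d_in, o$d_in, tolerance = 1e-12)
      expect_equal(bd$d_out, o$d_out, tolerance = 1e-12)
    }
  })

  expect_error(boundary_distance(label_mask(array(FALSE, dim = c(3, 3, 3)),
                                            c(1, 1, 1))), "empty")
  expect_error(boundary_distance(label_mask(array(TRUE, dim = c(3, 3, 3)),
                                            c(1, 1, 1))), "full grid")
})

test_that("inward shells reproduce iterated erosion on the 7^3 cube", {
  mk <- cube_mask(11L, 7L)
  dec <- inward_shells(mk, 1)
  counts <- vapply(dec$shells, mask_count, numeric(1))
  expect_equal(counts, c(218, 98, 26, 1))  # 7^3-5^3, 5^3-3^3, 3^3-1, 1

  # successive iterated-erosion differences are the same sets
  cur <- mk$data
  for (k in seq_along(dec$shells)) {
    eroded <- brute_erode(cur)
    expect_identical(dec$shells[[k]]$data, cur & !eroded)
    cur <- eroded
  }
  expect_false(any(cur))
})

test_that("inward shells partition the source mask; erosion oracle holds on random masks", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      mk <- random_blob_mask(c(14L, 13L, 12L))
      dec <- inward_shells(mk, 1)
      un <- array(FALSE, dim = dim(mk$data))
      tot <- 0
      for (s in dec$shells) {
        expect_false(any(un & s$data))   # pairwise disjoint
        un <- un | s$data
        tot <- tot + mask_count(s)
      }
      expect_identical(un, mk$data)      # union is exactly the mask
      expect_equal(tot, mask_count(mk))

      # isotropic grid, thickness = spacing: the first shell is exactly
      # the layer peeled off by one unit-ball erosion (deeper shells of a
      # digital erosion measure city-block rather than Euclidean distance
      # and are pinned by the convex-mask fixture instead)
      expect_identical(dec$shells[[1]]$data, mk$data & !brute_erode(mk$data))
      # monotonicity: shell k's distances all exceed shell k-1's lower bound
      bd <- boundary_distance(mk)
      for (k in seq_along(dec$shells)[-1])
        expect_gt(min(bd$d_in[dec$shells[[k]]$data]),
                  (k - 1) * dec$thickness_mm)
    }
  })

  # single-voxel mask: exactly one shell containing that voxel
  m <- array(FALSE, dim = c(4, 4, 4)); m[2, 3, 2] <- TRUE
  dec1 <- inward_shells(label_mask(m, c(1, 1, 1)), 1)
  expect_length(dec1$shells, 1)
  expect_identical(dec1$shells[[1]]$data, m)

  expect_error(inward_shells(cube_mask(), 0), "positive")
  expect_error(inward_shells(cube_mask(), -1), "positive")
})

test_that("outward shells are mm-banded, clipped and limitable", {
  # 1-voxel mask: first 1 mm shell is exactly the 6 face neighbors
  m <- array(FALSE, dim = c(7, 7, 7)); m[4, 4, 4] <- TRUE
  mk <- label_mask(m, c(1, 1, 1))
  dec <- outward_shells(mk, 1, n_shells = 1)
  expect_equal(mask_count(dec$shells[[1]]), 6)
  got <- which(dec$shells[[1]]$data, arr.ind = TRUE)
  expect_true(all(rowSums(abs(sweep(got, 2, c(4, 4, 4)))) == 1))

  # shells disjoint from the source mask, banded by brute-force distance
  withr::with_seed(31, {
    mk2 <- random_blob_mask(c(11L, 10L, 12L))
    dec2 <- outward_shells(mk2, 1, n_shells = 3)
    o <- brute_edt(mk2$data, mk2$spacing)
    for (k in seq_along(dec2$shells)) {
      expect_false(any(dec2$shells[[k]]$data & mk2$data))
      sel <- o$d_out > (k - 1) & o$d_out <= k
      expect_identical(dec2$shells[[k]]$data, array(sel, dim = dim(sel)))
    }
  })

  # degenerate limit mask: empty decomposition with a warning
  empty_limit <- label_mask(array(FALSE, dim = c(7, 7, 7)), c(1, 1, 1))
  expect_warning(dec3 <- outward_shells(mk, 1, n_shells = 2,
                                        limit_mask = empty_limit),
                 "no non-empty shells")
  expect_length(dec3$shells, 0)
})

test_that("margin regions are the first inward/outward 1 mm shells", {
  mk <- cube_mask(11L, 7L)
  mr <- margin_regions(mk)
  expect_equal(mask_count(mr$inner_1mm), 218)
  expect_false(any(mr$inner_1mm$data & mr$outer_1mm$data))
  # mask minus its inner margin is the 1 mm erosion
  eroded <- mk$data & !mr$inner_1mm$data
  expect_identical(eroded, brute_erode(mk$data))
})

test_that("boundary band spans both sides of the surface", {
  mk <- cube_mask(13L, 7L)
  band <- boundary_band(mk, 1)
  mr <- margin_regions(mk)
  expect_identical(band$data, mr$inner_1mm$data | mr$outer_1mm$data)

  o <- brute_edt(mk$data, mk$spacing)
  expect_identical(band$data,
                   array((o$d_in > 0 & o$d_in <= 1) |
                           (o$d_out > 0 & o$d_out <= 1), dim = dim(o$d_in)))

  # full-grid-minus-one mask: band is well-defined and small
  m <- array(TRUE, dim = c(6, 6, 6)); m[3, 3, 3] <- FALSE
  b2 <- boundary_band(label_mask(m, c(1, 1, 1)), 1)
  expect_equal(mask_count(b2), 7)  # the hole plus its 6 face neighbors

  expect_error(boundary_band(mk, 0), "positive")
})

test_that("contralateral mirroring preserves counts and is an involution", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[2:3, 2:4, 4:5] <- TRUE
  mk <- label_mask(m, c(1, 1, 1), "tumor")

  # reflection across x-plane at index c maps i to 2c - i
  ref <- contralateral_region(mk, axis = "x", coordinate = 3)
  expect_equal(mask_count(ref), mask_count(mk))
  idx <- which(mk$data, arr.ind = TRUE)
  expected <- idx; expected[, 3] <- 6L - idx[, 3]
  got <- which(ref$data, arr.ind = TRUE)
  expect_equal(unname(got[order(got[, 1], got[, 2], got[, 3]), ]),
               unname(expected[order(expected[, 1], expected[, 2],
                                     expected[, 3]), ]))

  # involution
  back <- contralateral_region(ref, axis = 3, coordinate = 3)
  expect_identical(back$data, mk$data)

  # half-integer plane between voxel columns
  ref2 <- contralateral_region(mk, axis = "x", coordinate = 3.5)
  expect_equal(mask_count(ref2), mask_count(mk))

  # mask touching the symmetry plane overlaps its own mirror
  m2 <- array(FALSE, dim = c(5, 5, 5)); m2[3, 3, 2:4] <- TRUE
  expect_error(contralateral_region(label_mask(m2, c(1, 1, 1)), "x", 3),
               "overlaps")
  # reflection exiting the grid
  expect_error(contralateral_region(mk, "x", 1), "exits the grid")
  # off-grid plane coordinate
  expect_error(contralateral_region(mk, "x", 3.25), "integer")
})
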