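test_that("threshold_air keeps air at and below the cut", {
  vol <- hu_volume(array(c(-1000, 0, -460, -459, 40, -461),
                         dim = c(6, 1, 1)), spacing = 0.5)
  air <- threshold_air(vol)
  expect_equal(as.vector(air), c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("threshold_air rejects non-finite voxels with a count", {
  v <- array(0, dim = c(2, 2, 2))
  v[c(1, 8)] <- NaN
  expect_error(threshold_air(hu_volume(v, 1)), "2 non-finite")
})

test_that("detect_tip finds the constructed phantom tip", {
  tip <- detect_tip(default_air())
  truth <- attr(default_phantom(), "truth")$tip_vox
  expect_lte(sqrt(sum((tip - truth)^2)), 2)
})

test_that("detect_tip errors on an all-air volume", {
  air <- array(TRUE, dim = c(8, 8, 8))
  expect_error(detect_tip(air), "all air")
})

test_that("detect_tip is equivariant under anterior-posterior shifts", {
  d <- c(21L, 30L, 21L)
  mk <- function(j0) {
    a <- array(TRUE, d)
    a[, j0:d[2], ] <- FALSE          # tissue block
    a[11, j0 - 2, 11] <- FALSE       # protruding tip voxel
    a[10:12, j0 - 1, 10:12] <- FALSE
    a
  }
  t1 <- detect_tip(mk(10))
  t2 <- detect_tip(mk(14))
  expect_equal(t2 - t1, c(0L, 4L, 0L))
})

test_that("the smallest sphere is the one-voxel-radius ball", {
  air <- array(TRUE, dim = c(9, 9, 9))
  attr(air, "spacing") <- rep(1, 3)
  vox <- rhinoflow:::.sphere_voxels(c(9L, 9L, 9L), rep(1, 3),
                                    c(5, 5, 5), 1)
  expect_equal(length(vox), 7) # center plus 6 face neighbors
})

test_that("oversized probe regions raise bounds errors naming the axis", {
  air <- default_air()
  tip <- detect_tip(air)
  expect_error(place_probes(air, tip, sphere_diam_mm = 70),
               "sphere exceeds grid bounds")
  expect_error(place_probes(air, tip, sphere_diam_mm = 8,
                            cuboid_dims_mm = c(200, 4, 3)),
               "cuboid exceeds grid bounds on the LR")
})

test_that("the cuboid lands inside the constructed cavity box", {
  dom <- default_domain()
  tr <- attr(default_phantom(), "truth")
  ijk <- rhinoflow:::.index_to_ijk(dim(dom$air_mask), dom$cuboid$voxels)
  cav <- tr$cavity_box
  expect_true(all(ijk[, 1] >= cav$i[1] - 1 & ijk[, 1] <= cav$i[2] + 1))
  expect_true(all(ijk[, 2] >= cav$j[1] - 1 & ijk[, 2] <= cav$j[2] + 1))
})

test_that("grow_airway keeps only the seeded component", {
  d <- c(12L, 12L, 12L)
  air <- array(FALSE, d)
  air[2:4, 2:4, 2:4] <- TRUE    # blob A
  air[8:10, 8:10, 8:10] <- TRUE # blob B
  comp <- rhinoflow:::flood26_cpp(as.vector(air), d,
                                  rhinoflow:::.grid_index(d, 3L, 3L, 3L))
  comp <- array(comp, d)
  expect_true(all(comp[2:4, 2:4, 2:4]))
  expect_false(any(comp[8:10, 8:10, 8:10]))
  # fully connected air: growth is the identity
  full <- array(TRUE, d)
  comp2 <- array(rhinoflow:::flood26_cpp(as.vector(full), d, 1L), d)
  expect_true(all(comp2))
})

test_that("extraction recovers lumen plus in-sphere exterior exactly", {
  vol <- default_phantom()
  tr <- attr(vol, "truth")
  dom <- default_domain()
  sph <- array(FALSE, dim(dom$air_mask))
  sph[dom$sphere$voxels] <- TRUE
  expected <- tr$lumen | (tr$exterior & sph)
  expect_true(all(dom$air_mask == expected))
  expect_gt(length(dom$open_cells), 0)
})

test_that("threshold and growth are idempotent and mask-conserving", {
  vol <- default_phantom()
  air <- threshold_air(vol)
  expect_true(all(threshold_air(vol) == air))
  dom <- default_domain()
  # regrowing the grown mask changes nothing
  pr <- list(sphere = dom$sphere, cuboid = dom$cuboid)
  class(pr) <- "probe_set"
  m <- dom$air_mask
  attr(m, "spacing") <- dom$spacing
  dom2 <- grow_airway(m, pr)
  expect_true(all(dom2$air_mask == dom$air_mask))
  # growth output is a subset of the thresholded air
  expect_true(all(!(dom$air_mask & !air)))
})

test_that("block_nostril plugs one side and keeps the other open", {
  dom <- default_domain()
  expect_identical(block_nostril(dom, "none"), dom)
  db <- block_nostril(dom, "right")
  expect_equal(db$blocked_side, "right")
  expect_gt(length(db$plug_voxels), 0)
  expect_false(any(db$air_mask[db$plug_voxels]))
  # plug voxels sit on the right half just behind the face
  ijk <- rhinoflow:::.index_to_ijk(dim(dom$air_mask), db$plug_voxels)
  expect_true(all(ijk[, 1] < (dim(dom$air_mask)[1] + 1) / 2))
  expect_true(all(ijk[, 2] >= dom$face_j & ijk[, 2] <= dom$face_j + 2))
})

test_that("blocking both nostrils severs the airway", {
  dom <- default_domain()
  one <- block_nostril(dom, "left")
  expect_error(block_nostril(one, "right"), "no airway path")
})
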