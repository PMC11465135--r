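test_that("mask_volume_ml converts voxel counts at native spacing", {
  bin <- array(FALSE, c(12, 12, 12)); bin[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mask_volume_ml(bin, c(1, 1, 1)), 1.0)
  bin2 <- array(FALSE, c(4, 4, 4)); bin2[1:4, 1:4, 1:4] <- TRUE
  expect_equal(mask_volume_ml(bin2, c(0.5, 0.5, 0.5)), 0.008)
  empty <- mask_volume_ml(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "absent"))
  expect_error(mask_volume_ml(bin, c(0, 1, 1)), "spacing")
})

test_that("digitized ellipsoid volume matches the closed form", {
  bin <- ellipsoid_mask(c(50, 30, 20))
  vol <- mask_volume_ml(bin, c(1, 1, 1))
  truth <- 4 * pi / 3 * 50 * 30 * 20 / 1000
  expect_lt(abs(vol - truth) / truth, 0.015)
})

test_that("principal_frame recovers analytic ellipsoid axes", {
  bin <- ellipsoid_mask(c(50, 30, 20))
  fr <- principal_frame(bin, as_label(bin))
  # first axis within 2 degrees of x
  ang <- acos(abs(sum(fr$axes[, 1] * c(1, 0, 0)))) * 180 / pi
  expect_lt(ang, 2)
  expect_true(all(diff(fr$variances) <= 0))
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-8)
  expect_equal(det(fr$axes), 1, tolerance = 1e-8)

  # equivariance: rotated mask has rotated axes
  spec <- phantom_spec("ellipsoid", c(50, 30, 20), rotation = c(0, 0, 25))
  mm <- make_mask(spec, c(130, 110, 60))
  fr_rot <- principal_frame(mm$mask$data > 0, mm$mask)
  R <- rotation_matrix(c(0, 0, 25))
  expected <- R %*% c(1, 0, 0)
  ang_rot <- acos(abs(sum(fr_rot$axes[, 1] * expected))) * 180 / pi
  expect_lt(ang_rot, 2)
})

test_that("sphere eigenvalues are isotropic", {
  bin <- sphere_mask(20)
  fr <- principal_frame(bin, as_label(bin))
  expect_lt(diff(range(fr$variances)) / mean(fr$variances), 0.02)
})

test_that("degenerate point clouds raise a rank-naming error", {
  flat <- array(FALSE, c(10, 10, 3))
  flat[2:9, 2:9, 2] <- TRUE   # coplanar
  expect_error(principal_frame(flat, as_label(flat)), "rank 2")
  few <- array(FALSE, c(5, 5, 5)); few[2, 2, 2] <- TRUE
  expect_error(principal_frame(few, as_label(few)), ">= 4")
})

test_that("obb_extents measures ellipsoid axes with voxel compensation", {
  bin <- ellipsoid_mask(c(50, 30, 20))
  g <- as_label(bin)
  fr <- principal_frame(bin, g)
  ext <- obb_extents(bin, fr, g)
  expect_equal(ext, c(100, 60, 40), tolerance = 2 / 40)
  # slab dialect: with 1-voxel compensation a 4-voxel slab measures 4 mm
  # and a single voxel spans (1,1,1) (center-projection span 0 + 1 mm)
  one <- array(FALSE, c(7, 7, 7)); one[2:5, 3, 4] <- TRUE
  fr1 <- list(center = c(0, 0, 0), axes = diag(3), variances = c(3, 2, 1))
  class(fr1) <- "principal_frame"
  ext1 <- obb_extents(one, fr1, as_label(one), compensation_voxels = 1)
  expect_equal(ext1, c(4, 1, 1))
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(obb_extents(single, fr1, as_label(single),
                           compensation_voxels = 1), c(1, 1, 1))
})

test_that("label_axes assigns extents to anatomical directions", {
  # identity frame ordered z, x, y by variance: PC1 along S-I
  fr <- structure(list(center = c(0, 0, 0),
                       axes = cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                       variances = c(9, 4, 1)), class = "principal_frame")
  lw <- label_axes(fr, c(100, 60, 40), "right")
  expect_equal(lw[["length_mm"]], 100)
  expect_equal(lw[["width_mm"]], 60)
  expect_equal(lw[["thickness_mm"]], 40)
  # swapping side leaves values unchanged
  lw2 <- label_axes(fr, c(100, 60, 40), "left")
  expect_equal(unclass(lw2)[1:3], unclass(lw)[1:3])

  # tilt below 45 degrees keeps the assignment stable
  for (tilt in c(10, 30, 44)) {
    R <- rotation_matrix(c(tilt, 0, 0))  # tilt in the coronal plane
    frt <- structure(list(center = c(0, 0, 0),
                          axes = R %*% fr$axes, variances = c(9, 4, 1)),
                     class = "principal_frame")
    expect_equal(label_axes(frt, c(100, 60, 40), "right")[["length_mm"]],
                 100, info = paste("tilt", tilt))
  }
})

test_that("measure_kidney recovers phantom truth and is rotation-stable", {
  spec <- phantom_spec("ellipsoid", c(30, 20, 50))
  mm <- make_mask(spec, c(80, 60, 120))
  m <- measure_kidney(mm$mask, "right")
  expect_equal(m$volume_ml, mm$truth$volume_ml, tolerance = 0.02)
  expect_equal(m$length_mm, 100, tolerance = 2 / 100)
  expect_equal(m$width_mm, 60, tolerance = 2 / 60)
  expect_equal(m$thickness_mm, 40, tolerance = 2 / 40)

  rot <- phantom_spec("ellipsoid", c(30, 20, 50),
                      rotation = c(20, -30, 15))
  mr <- make_mask(rot, c(110, 100, 120))
  m2 <- measure_kidney(mr$mask, "right")
  expect_equal(m2$volume_ml, m$volume_ml, tolerance = 0.02)
  expect_equal(m2$length_mm, m$length_mm, tolerance = 2 / 100)
  expect_equal(m2$width_mm, m$width_mm, tolerance = 2 / 60)
  expect_equal(m2$thickness_mm, m$thickness_mm, tolerance = 2 / 40)
})

test_that("sphere measures 2r on every anatomical axis", {
  spec <- phantom_spec("ellipsoid", c(30, 30, 30))
  mm <- make_mask(spec, c(80, 80, 80))
  m <- measure_kidney(mm$mask, "right")
  expect_equal(m$length_mm, 60, tolerance = 2 / 60)
  expect_equal(m$width_mm, 60, tolerance = 2 / 60)
  expect_equal(m$thickness_mm, 60, tolerance = 2 / 60)
})

test_that("absent kidney yields an absent-valued record, not zeros", {
  lab <- as_label(sphere_mask(6), class_id = 1L)
  m <- measure_kidney(lab, "left")
  expect_false(m$present)
  expect_true(is.na(m$volume_ml) && is.na(m$length_mm))
  tab <- measure_kidneys(lab)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$present, c(TRUE, FALSE))
})

test_that("ellipsoid_volume implements pi/6 l w t on reference axes", {
  expect_equal(ellipsoid_volume(0, 60, 40), 0)
  # pi/6 (2a)(2b)(2c) identity with the analytic ellipsoid volume
  expect_equal(ellipsoid_volume(100, 60, 40), 4 * pi / 3 * 50 * 30 * 20 / 1000)
  expect_equal(ellipsoid_volume(113.96, 66.28, 49.18),
               pi / 6 * 113.96 * 66.28 * 49.18 / 1000)
  expect_equal(ellipsoid_volume(113.96, 66.28, 49.18), 194.5, tolerance = 0.01 / 194.5)
  expect_error(ellipsoid_volume(-1, 2, 3), "non-negative")
})

test_that("PCA-OBB volume does not exceed the axis-aligned box volume", {
  set.seed(21)
  for (i in 1:5) {
    spec <- phantom_spec("ellipsoid", c(35, 22, 48),
                         rotation = runif(3, -40, 40))
    mm <- make_mask(spec, c(120, 110, 120))
    bin <- mm$mask$data > 0
    fr <- principal_frame(bin, mm$mask)
    obb <- prod(obb_extents(bin, fr, mm$mask))
    idx <- arrayInd(which(bin), dim(bin))
    aabb <- prod(apply(idx, 2, function(v) diff(range(v)) + 1))
    expect_lte(obb, aabb * 1.001)
  }
})
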