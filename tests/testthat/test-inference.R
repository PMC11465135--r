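constant_predictor <- function(scores, patch = 8L) {
  predictor(patch, length(scores), function(p, origin, imgdim) {
    d <- dim(p)
    array(rep(scores, each = prod(d)), c(d, length(scores)))
  })
}

norm_grid <- function(dim, value = 0.5, spacing = c(1, 1, 1)) {
  scalar_grid(array(value, dim), spacing)
}

test_that("sliding window reproduces a constant predictor exactly", {
  img <- norm_grid(c(20, 14, 9))
  sc <- sliding_window_predict(img, constant_predictor(c(0.2, 0.5, 0.3)), 0.5)
  expect_equal(dim(sc$scores), c(20, 14, 9, 3))
  expect_true(all(sc$coverage >= 1))
  for (cl in 1:3)
    expect_lt(max(abs(sc$scores[, , , cl] - c(0.2, 0.5, 0.3)[cl])), 1e-14)
})

test_that("tiling arithmetic matches the enumerated origin set", {
  img <- norm_grid(c(144, 96, 96))
  p <- constant_predictor(c(1, 0, 0), patch = 96L)
  sc <- sliding_window_predict(img, p, overlap = 0.5)
  expect_equal(sc$origins[[1]], c(0L, 48L))
  expect_equal(sc$origins[[2]], 0L)
  expect_equal(sc$origins[[3]], 0L)
  expect_equal(prod(lengths(sc$origins)), 2)
  # voxels 48-95 on axis 1 covered by both patches
  expect_true(all(sc$coverage[49:96, , ] == 2))
  expect_true(all(sc$coverage[1:48, , ] == 1))
  expect_true(all(sc$coverage[97:144, , ] == 1))
  # degenerate tiling: image equal to the patch
  sc1 <- sliding_window_predict(norm_grid(c(96, 96, 96)), p, 0.5)
  expect_equal(prod(lengths(sc1$origins)), 1)
})

test_that("coverage is complete for random shapes and overlaps", {
  set.seed(31)
  for (i in 1:8) {
    d <- sample(5:40, 3, replace = TRUE)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    sc <- sliding_window_predict(norm_grid(d),
                                 constant_predictor(c(0.6, 0.4), patch = 16L),
                                 ov)
    expect_true(all(sc$coverage >= 1))
    expect_equal(dim(sc$coverage), d)
  }
  expect_error(sliding_window_predict(norm_grid(c(8, 8, 8)),
                                      constant_predictor(c(1, 0)), 1),
               "overlap")
})

test_that("patch averaging commutes with a global shift for linear scores", {
  set.seed(5)
  img <- scalar_grid(array(runif(18^3), c(18, 18, 18)), c(1, 1, 1))
  lin <- function(offset) predictor(8L, 2L, function(p, o, d) {
    out <- array(0, c(dim(p), 2))
    out[, , , 1] <- p + offset
    out[, , , 2] <- -p
    out
  })
  s0 <- sliding_window_predict(img, lin(0), 0.5)$scores
  s1 <- sliding_window_predict(img, lin(0.3), 0.5)$scores
  expect_equal(s1[, , , 1], s0[, , , 1] + 0.3, tolerance = 1e-12)
})

test_that("predictor contract violations are reported", {
  bad <- predictor(8L, 3L, function(p, o, d) array(0, c(2, 2, 2, 3)))
  expect_error(sliding_window_predict(norm_grid(c(10, 10, 10)), bad, 0.5),
               "contract")
})

test_that("argmax labeling uses the lowest-class tie rule and shift invariance", {
  mk <- function(v) {
    sc <- array(rep(v, each = 8), c(2, 2, 2, 3))
    structure(list(scores = sc, coverage = array(1L, c(2, 2, 2)),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3), origins = list(0L, 0L, 0L)),
              class = "class_score_grid")
  }
  expect_true(all(scores_to_labels(mk(c(0.1, 0.8, 0.1)))$data == 1L))
  expect_true(all(scores_to_labels(mk(c(0.5, 0.5, 0)))$data == 0L))
  expect_true(all(scores_to_labels(mk(c(0.2, 0.3, 0.5)))$data == 2L))
  # shift invariance of argmax
  expect_identical(scores_to_labels(mk(c(0.1, 0.8, 0.1) + 5))$data,
                   scores_to_labels(mk(c(0.1, 0.8, 0.1)))$data)
})

test_that("largest_component keeps the biggest 26-connected segment", {
  lab <- array(0L, c(30, 20, 20))
  lab[2:11, 2:11, 2:11] <- 1L              # 1000 voxels
  lab[25:26, 15:16, 12:13] <- 1L           # 8 voxels, separate
  lab[28, 18, 18] <- 1L                    # singleton: diagonal-adjacent test
  lab[29, 19, 19] <- 1L                    # 26-connected to the above
  out <- largest_component(as_label(lab), 1L)
  expect_equal(sum(out), 1000)
  expect_false(attr(out, "absent"))
  # single component is returned unchanged
  one <- array(FALSE, c(8, 8, 8)); one[2:4, 2:4, 2:4] <- TRUE
  expect_equal(sum(largest_component(as_label(one, 2L), 2L)), 27)
  # absent class: empty mask plus flag, not an error
  ab <- largest_component(as_label(one, 2L), 1L)
  expect_true(attr(ab, "absent"))
  expect_equal(sum(ab), 0)
  expect_error(largest_component(as_label(one), 0), "kidney class")
})

test_that("equal-size components tie toward the lowest linear index", {
  lab <- array(0L, c(20, 6, 6))
  lab[15:16, 2:3, 2:3] <- 1L   # 8 voxels, higher linear index
  lab[2:3, 2:3, 2:3] <- 1L     # 8 voxels, lower linear index
  out <- largest_component(as_label(lab), 1L)
  expect_equal(sum(out), 8)
  expect_true(out[2, 2, 2])
  expect_false(out[15, 2, 2])
})

test_that("26-connectivity joins diagonal neighbours", {
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 1L
  lab[2, 2, 2] <- 1L   # corner-diagonal neighbour
  out <- largest_component(as_label(lab), 1L)
  expect_equal(sum(out), 2)
})

test_that("upsample_binary is threshold-monotone and volume-faithful", {
  bin <- sphere_mask(20)
  g <- as_label(bin)
  down <- resample(g, 1.5)
  counts <- vapply(c(0.3, 0.5, 0.7), function(t)
    sum(upsample_binary(down, g, threshold = t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # T = 0.5 mildly erodes a strongly curved surface (double thresholding
  # of trilinear-interpolated binary data); the validated threshold
  # recovers the volume -- the reason the threshold search exists
  v0 <- mask_volume_ml(bin, c(1, 1, 1))
  v_half <- mask_volume_ml(upsample_binary(down, g, threshold = 0.5),
                           c(1, 1, 1))
  expect_lt(abs(v_half - v0) / v0, 0.05)
  prob <- resample_to_geometry(
    scalar_grid((down$data > 0) * 1, down$spacing, down$origin),
    g, "trilinear")$data
  sel <- select_threshold(list(list(prob = prob, reference = bin)))
  expect_gte(as.numeric(dice(prob >= sel$threshold, bin)),
             as.numeric(dice(prob >= 0.5, bin)))
  # some grid threshold matches the reference volume within 3% -- the
  # existence that motivates validated threshold selection
  verr <- vapply(sel$table$threshold[-1], function(t)
    abs(mask_volume_ml(prob >= t, c(1, 1, 1)) - v0) / v0, numeric(1))
  expect_lt(min(verr), 0.03)
  # threshold 0.5 at identical spacing is the identity
  same <- upsample_binary(g, g, threshold = 0.5)
  expect_equal(same, bin, ignore_attr = TRUE)
  expect_error(upsample_binary(g, g, threshold = 0), "threshold")
})

test_that("select_threshold returns the exhaustive-grid argmax with tie rule", {
  set.seed(8)
  bin <- sphere_mask(10)
  down <- resample(as_label(bin), 1.5)
  prob <- resample_to_geometry(
    scalar_grid((down$data > 0) * 1, down$spacing, down$origin),
    as_label(bin), "trilinear")$data
  ref <- bin
  sel <- select_threshold(list(list(prob = prob, reference = ref)))
  # oracle: exhaustive evaluation over the same grid
  ts <- seq(0, 1, by = 0.05)
  ds <- vapply(ts, function(t) as.numeric(dice(prob >= t, ref)), numeric(1))
  expect_equal(sel$table$mean_dsc, ds)
  expect_equal(sel$threshold, ts[which.max(ds)])
  expect_true(all(sel$table$mean_dsc <= max(ds)))

  # reference equal to the case at every threshold -> grid minimum by ties
  flat <- list(list(prob = (bin) * 1, reference = bin))
  expect_equal(select_threshold(flat)$threshold, 0.05)
  expect_error(select_threshold(list()), "at least one")
})

test_that("reference predictor is deterministic and silent on background", {
  w <- protocol_window("ce")
  img <- window_normalize(scalar_grid(array(-50, c(40, 30, 20)),
                                      c(1, 1, 1)), w)
  pred <- reference_hu_predictor(w, patch_size = 32L)
  s1 <- sliding_window_predict(img, pred, 0.5)
  s2 <- sliding_window_predict(img, pred, 0.5)
  expect_identical(s1$scores, s2$scores)
  lab <- scores_to_labels(s1)
  expect_true(all(lab$data == 0L))
  expect_true(attr(largest_component(lab, 1), "absent"))
  expect_true(attr(largest_component(lab, 2), "absent"))
})

test_that("post-processing argmax + largest-component is idempotent", {
  set.seed(13)
  lab <- array(sample(0:2, 16^3, TRUE, prob = c(0.9, 0.05, 0.05)),
               rep(16, 3))
  g <- as_label(lab > 0)  # arbitrary structure
  once <- array(0L, dim(lab))
  for (cl in 1:2) once[largest_component(lab, cl)] <- cl
  twice <- array(0L, dim(lab))
  for (cl in 1:2) twice[largest_component(once, cl)] <- cl
  expect_identical(twice, once)
})
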