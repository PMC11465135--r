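#' Per-patch predictor contract
#'
#' A predictor maps a normalized intensity patch to a per-class score
#' lattice of the same spatial shape.  The function is called as
#' `fn(patch, origin, image_dim)` where `origin` is the 0-based voxel origin
#' of the patch inside the (possibly padded) image and `image_dim` that
#' image's shape, so position-aware backends (e.g. right/left assignment at
#' the midsagittal plane) are expressible.  Output must be deterministic
#' given identical input.
#'
#' @param patch_size Patch edge length per axis, voxels (scalar or length-3).
#' @param n_classes Number of classes (default 3).
#' @param fn Prediction function, `fn(patch, origin, image_dim)` returning a
#'   4-D array `c(dim(patch), n_classes)`.
#' @return An object of class `kidney_predictor`.
#' @export
predictor <- function(patch_size, n_classes = 3L, fn) {
  structure(list(patch_size = rep_len(as.integer(patch_size), 3L),
                 n_classes = as.integer(n_classes), fn = fn),
            class = "kidney_predictor")
}

sliding_origins <- function(n, p, overlap) {
  if (n <= p) return(0L)
  stride <- max(1L, as.integer(round(p * (1 - overlap))))
  og <- seq.int(0L, n - p, by = stride)
  if (og[length(og)] != n - p) og <- c(og, n - p)
  og
}

#' Sliding-window prediction over a full volume
#'
#' Tiles the image with overlapping patches (stride
#' `patch_size * (1 - overlap)`, final patch aligned to the image edge),
#' runs the predictor on every patch, and averages the scores of
#' overlapping voxels arithmetically.  Images smaller than the patch are
#' edge-padded (replication) and cropped back.
#'
#' @param image A normalized [scalar_grid()] (values in `[0, 1]`).
#' @param pred A [predictor()].
#' @param overlap Patch overlap fraction in `[0, 1)`; default 0.5.
#' @return An object of class `class_score_grid`: list with `scores` (4-D
#'   array, last axis = class), `coverage` (per-voxel contributing-patch
#'   count, >= 1 everywhere), `geometry` (the input grid geometry) and
#'   `origins` (per-axis patch origin lists, 0-based, in padded coords).
#' @export
sliding_window_predict <- function(image, pred, overlap = 0.5) {
  stopifnot(inherits(pred, "kidney_predictor"))
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  img <- image$data
  d0 <- dim(img)
  p <- pred$patch_size
  padn <- pmax(p - d0, 0L)
  if (any(padn > 0L)) {
    dp <- d0 + padn
    idx <- lapply(1:3, function(ax) pmin(seq_len(dp[ax]), d0[ax]))
    img <- img[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  d <- dim(img)
  og <- lapply(1:3, function(ax) sliding_origins(d[ax], p[ax], overlap))
  acc <- array(0, c(d, pred$n_classes))
  cov <- array(0L, d)
  for (oz in og[[3]]) for (oy in og[[2]]) for (ox in og[[1]]) {
    ix <- seq.int(ox + 1L, length.out = p[1])
    iy <- seq.int(oy + 1L, length.out = p[2])
    iz <- seq.int(oz + 1L, length.out = p[3])
    patch <- img[ix, iy, iz, drop = FALSE]
    sc <- pred$fn(patch, c(ox, oy, oz), d)
    if (!all(dim(sc) == c(p, pred$n_classes)))
      stop("predictor output shape (", paste(dim(sc), collapse = "x"),
           ") does not match contract (",
           paste(c(p, pred$n_classes), collapse = "x"), ")", call. = FALSE)
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + sc
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1L
  }
  scores <- acc / as.vector(cov)  # recycles coverage over the class axis
  if (any(padn > 0L)) {
    scores <- scores[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), ,
                     drop = FALSE]
    cov <- cov[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  }
  structure(list(scores = scores, coverage = cov,
                 spacing = image$spacing, origin = image$origin,
                 direction = image$direction, origins = og),
            class = "class_score_grid")
}

#' Convert averaged class scores to a label map
#'
#' Per-voxel argmax of the averaged scores; ties are broken toward the
#' lower class index.
#'
#' @param scores A `class_score_grid` from [sliding_window_predict()].
#' @return A [label_grid()].
#' @export
scores_to_labels <- function(scores) {
  stopifnot(inherits(scores, "class_score_grid"))
  lab <- argmax_labels(scores$scores)
  label_grid(lab, scores$spacing, scores$origin, scores$direction)
}

#' Keep only the largest connected component of a kidney class
#'
#' Connected component analysis (26-neighbourhood) of one kidney class,
#' retaining only the largest segment.  Equal-size ties keep the component
#' containing the lowest linear voxel index.  An absent class yields an
#' empty mask flagged via `attr(, "absent")` rather than an error.
#'
#' @param mask A [label_grid()] or binary/integer 3-D array.
#' @param class_id Kidney class, 1 (right) or 2 (left).
#' @return Binary (logical) 3-D array with attribute `absent`.
#' @export
largest_component <- function(mask, class_id) {
  if (!class_id %in% 1:2)
    stop("class_id must be a kidney class (1 or 2)", call. = FALSE)
  data <- if (inherits(mask, "label_grid")) mask$data else mask
  bin <- data == class_id
  if (!any(bin)) {
    out <- array(FALSE, dim(data))
    attr(out, "absent") <- TRUE
    return(out)
  }
  lab <- cpp_label_components26(bin, dim(bin))
  sizes <- tabulate(lab)
  # components are numbered in discovery order under a linear scan, so the
  # smallest id among maximal sizes is the tie-rule winner
  keep <- which(sizes == max(sizes))[1]
  out <- lab == keep
  attr(out, "absent") <- FALSE
  out
}

#' Upsample a binary mask to a target geometry with thresholding
#'
#' Trilinear interpolation of the mask indicator onto the target lattice
#' followed by `>= threshold` binarization.  Used to bring masks processed
#' at 1.5 mm isotropic spacing back to the original CT resolution.
#'
#' @param mask Binary 3-D array or [label_grid()] at processing spacing;
#'   when an array is given, `geometry` must describe its lattice via a
#'   grid object in `source_geometry`.
#' @param target_geometry Grid or geometry list describing the output
#'   lattice.
#' @param threshold Binarization threshold in (0, 1).
#' @param source_geometry Geometry of `mask` when `mask` is a bare array.
#' @return Binary (logical) 3-D array on the target lattice.
#' @export
upsample_binary <- function(mask, target_geometry, threshold = 0.5,
                            source_geometry = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (inherits(mask, "label_grid")) {
    src <- with_data(mask, (mask$data > 0) * 1, label = FALSE)
  } else {
    if (is.null(source_geometry))
      stop("source_geometry required for a bare mask array", call. = FALSE)
    src <- scalar_grid((mask > 0) * 1, source_geometry$spacing,
                       source_geometry$origin, source_geometry$direction)
  }
  out <- resample_to_geometry(src, target_geometry, "trilinear")
  out$data >= threshold
}

#' Select the upsampling threshold on validation cases
#'
#' Evaluates a threshold grid over `[0, 1]` and returns the value
#' maximizing mean Dice similarity over the cases (ties resolved toward the
#' lowest threshold), together with the full audit table.
#'
#' @param cases List of cases, each a list with `prob` (probability or
#'   interpolated-indicator 3-D array) and `reference` (binary 3-D array or
#'   [label_grid()], foreground = any kidney class).
#' @param grid_step Threshold grid step; default 0.05.
#' @return List with `threshold` (selected value) and `table`
#'   (data.frame of threshold and mean_dsc).
#' @export
select_threshold <- function(cases, grid_step = 0.05) {
  if (length(cases) < 1L)
    stop("at least one validation case is required", call. = FALSE)
  ts <- seq(0, 1, by = grid_step)
  refs <- lapply(cases, function(cs) {
    r <- cs$reference
    if (inherits(r, "label_grid")) r$data > 0 else r > 0
  })
  mean_dsc <- vapply(ts, function(t) {
    mean(vapply(seq_along(cases), function(i)
      dice(cases[[i]]$prob >= t, refs[[i]]), numeric(1)))
  }, numeric(1))
  best <- ts[which(mean_dsc >= max(mean_dsc) - 1e-12)[1]]
  list(threshold = best, table = data.frame(threshold = ts,
                                            mean_dsc = mean_dsc))
}

#' Reference intensity-model predictor
#'
#' A non-learned backend implementing the predictor contract so the full
#' pipeline runs end-to-end without network weights.  Kidney score at a
#' voxel is `exp(-sharpness * (v - 0.5)^2)` where `v` is the window-
#' normalized intensity (0.5 = window center), after a light box smoothing
#' of the patch (noise suppression); the background score is its
#' complement.  Kidney score mass is assigned to the right (class 1) or
#' left (class 2) kidney by the voxel's position relative to the volume
#' midsagittal plane (+x is patient right in the canonical RAS frame).
#'
#' @param window The protocol [window_spec()] (the predictor operates on
#'   images normalized with this window).
#' @param decision_level Normalized intensity at which the kidney score
#'   crosses 0.5, i.e. the kidney/background decision boundary.  Soft
#'   tissue and fat fall below both protocol windows (normalized 0) while
#'   kidney parenchyma sits near 0.40 (CE, median 171 HU under 200/300) or
#'   0.28 (NC, median 28 HU under 65/170); the default 0.17 approximates
#'   half the kidney's normalized density under either window, so boundary
#'   partial-volume voxels split without systematic erosion or dilation.
#' @param score_sharpness Positive scalar controlling the width of the
#'   intensity response around the window center; by default derived from
#'   `decision_level` as `log(2) / (0.5 - decision_level)^2`.
#' @param patch_size Patch edge length, voxels.
#' @param smooth_radius Box-smoothing radius in voxels (0 disables).
#' @return A [predictor()].
#' @export
reference_hu_predictor <- function(window, decision_level = 0.17,
                                   score_sharpness = NULL,
                                   patch_size = 96L, smooth_radius = 1L) {
  stopifnot(inherits(window, "window_spec"),
            decision_level > 0, decision_level < 0.5)
  if (is.null(score_sharpness))
    score_sharpness <- log(2) / (0.5 - decision_level)^2
  stopifnot(score_sharpness > 0)
  fn <- function(patch, origin, image_dim) {
    v <- patch
    if (smooth_radius > 0) v <- box_smooth(v, smooth_radius)
    k <- exp(-score_sharpness * (v - 0.5)^2)
    xglob <- origin[1] + seq_len(dim(patch)[1]) - 1L
    right <- (xglob >= (image_dim[1] - 1) / 2) * 1
    d <- dim(patch)
    rightmask <- array(rep(right, times = d[2] * d[3]), d)
    out <- array(0, c(d, 3L))
    out[, , , 1] <- 1 - k
    out[, , , 2] <- k * rightmask
    out[, , , 3] <- k * (1 - rightmask)
    out
  }
  predictor(patch_size, 3L, fn)
}

#' Separable box smoothing of a 3-D array
#'
#' Running mean of half-width `radius` along each axis in turn, with
#' replicated edges.
#'
#' @param x 3-D numeric array.
#' @param radius Half-width in voxels.
#' @return Smoothed array of the same shape.
#' @export
box_smooth <- function(x, radius = 1L) {
  d <- dim(x)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    perm <- c(ax, setdiff(1:3, ax))
    y <- aperm(x, perm)
    m <- matrix(y, nrow = n)
    acc <- m
    cnt <- rep(1, n)
    for (r in seq_len(radius)) {
      up <- m[pmin(seq_len(n) + r, n), , drop = FALSE]
      dn <- m[pmax(seq_len(n) - r, 1), , drop = FALSE]
      acc <- acc + up + dn
      cnt <- cnt + 2
    }
    y <- acc / cnt
    dim(y) <- d[perm]
    x <- aperm(y, order(perm))
  }
  x
}
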