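#' Intensity window specification
#'
#' CT display/normalization window given as level/width in Hounsfield units.
#' The clamp range is `[level - width/2, level + width/2]`.  The protocols
#' used throughout the package are 65/170 HU for noncontrast (NC) and
#' 200/300 HU for contrast-enhanced (CE) imaging, chosen from the kidney HU
#' distributions of the two protocols.
#'
#' @param level Window level, HU.
#' @param width Window width, HU; must be > 0.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(level, width) {
  if (!is.finite(width) || width <= 0)
    stop("window width must be positive", call. = FALSE)
  structure(list(level = level, width = width), class = "window_spec")
}

#' Default window for a protocol
#' @param protocol `"ce"` or `"nc"`.
#' @return A [window_spec()]: 200/300 HU for CE, 65/170 HU for NC.
#' @export
protocol_window <- function(protocol = c("ce", "nc")) {
  protocol <- match.arg(protocol)
  if (protocol == "ce") window_spec(200, 300) else window_spec(65, 170)
}

#' Window and min-max normalize a volume
#'
#' Clamps intensities to the window range and maps it affinely onto
#' `[0, 1]`: the lower window bound maps to 0, the upper to 1, the level to
#' 0.5.  Monotone non-decreasing in HU.
#'
#' @param grid A [scalar_grid()] in HU.
#' @param window A [window_spec()].
#' @return A [scalar_grid()] with values in `[0, 1]`.
#' @export
window_normalize <- function(grid, window) {
  stopifnot(inherits(window, "window_spec"))
  lo <- window$level - window$width / 2
  v <- pmin(pmax(grid$data, lo), lo + window$width)
  out <- (v - lo) / window$width
  dim(out) <- dim(grid$data)
  with_data(grid, out, label = FALSE)
}

# output lattice covering the same physical field of view at new spacing,
# with the FOV center preserved
resampled_geometry <- function(grid, target_spacing) {
  n <- dim(grid$data)
  s <- grid$spacing
  t <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("target spacing must be positive", call. = FALSE)
  m <- pmax(1L, as.integer(round(n * s / t)))
  origin <- grid$origin +
    as.vector(grid$direction %*% ((s * (n - 1) - t * (m - 1)) / 2))
  list(dim = m, spacing = t, origin = origin, direction = grid$direction)
}

# map from 0-based output indices to continuous 0-based source indices
index_map <- function(src, out) {
  M <- diag(1 / src$spacing) %*% t(src$direction)
  A <- M %*% (out$direction %*% diag(out$spacing))
  b <- as.vector(M %*% (out$origin - src$origin))
  cbind(A, b)
}

sample_array <- function(data, src_geom, out_geom, mode) {
  map <- index_map(src_geom, out_geom)
  cpp_resample_affine(as.numeric(data), dim(data), as.integer(out_geom$dim),
                      map, identical(mode, "nearest"))
}

#' Resample a grid to a new voxel spacing
#'
#' Scalar grids are interpolated trilinearly (or by nearest neighbour);
#' label grids are resampled by trilinear interpolation of per-class
#' indicator functions followed by argmax (ties toward the lower class
#' index), or by nearest neighbour when `mode = "nearest"`.  The physical
#' field of view and its center are preserved; output shape per axis is
#' `round(extent / target_spacing)`.
#'
#' @param grid A [scalar_grid()] or [label_grid()].
#' @param target_spacing Numeric scalar or length-3, mm.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A grid of the same kind at the new spacing.
#' @export
resample <- function(grid, target_spacing, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  geom <- resampled_geometry(grid, target_spacing)
  resample_to_geometry(grid, geom, mode)
}

#' Resample a grid onto an explicit target geometry
#'
#' @param grid Source grid.
#' @param geometry A grid or a list with `dim`, `spacing`, `origin`,
#'   `direction` describing the target lattice.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return Grid of the same kind as `grid` on the target lattice.
#' @export
resample_to_geometry <- function(grid, geometry,
                                 mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (inherits(geometry, "scalar_grid"))
    geometry <- list(dim = dim(geometry$data), spacing = geometry$spacing,
                     origin = geometry$origin, direction = geometry$direction)
  if (any(geometry$dim < 1L))
    stop("resampling would produce an empty lattice", call. = FALSE)
  is_label <- inherits(grid, "label_grid")
  if (is_label && mode == "trilinear") {
    classes <- 0:2
    scores <- lapply(classes, function(cl)
      sample_array(grid$data == cl, grid, geometry, "trilinear"))
    lab <- max.col(do.call(cbind, lapply(scores, as.vector)),
                   ties.method = "first") - 1L
    dim(lab) <- geometry$dim
    out <- lab
  } else {
    out <- sample_array(grid$data, grid, geometry, mode)
    if (is_label) storage.mode(out) <- "integer"
  }
  if (is_label)
    label_grid(out, geometry$spacing, geometry$origin, geometry$direction)
  else
    scalar_grid(out, geometry$spacing, geometry$origin, geometry$direction)
}

#' One-hot encode a label map
#'
#' @param mask A [label_grid()] or integer array.
#' @param n_classes Number of classes (default 3: background, right kidney,
#'   left kidney).
#' @return 4-D numeric array `c(dim(mask), n_classes)`; channel `c` is the
#'   indicator of class `c - 1`, so channels sum to 1 at every voxel.
#' @export
one_hot <- function(mask, n_classes = 3L) {
  data <- if (inherits(mask, "label_grid")) mask$data else mask
  if (max(data) >= n_classes)
    stop("label ", max(data), " >= n_classes = ", n_classes, call. = FALSE)
  out <- vapply(seq_len(n_classes) - 1L, function(cl) (data == cl) * 1,
                FUN.VALUE = numeric(length(data)))
  dim(out) <- c(dim(data), n_classes)
  out
}

#' Collapse a one-hot / score stack to labels by argmax
#'
#' Ties are broken toward the lower class index.
#'
#' @param stack 4-D array, last dimension indexing classes.
#' @return Integer array of class labels (0-based).
#' @export
argmax_labels <- function(stack) {
  d <- dim(stack)
  lab <- max.col(matrix(stack, ncol = d[4]), ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  lab
}

#' Augmentation configuration
#'
#' Training-time augmentation bundle: random patch extraction (biased toward
#' patches containing foreground with probability `foreground_bias`), random
#' flips along the listed axes, random intensity shifting (uniform offset in
#' `(-intensity_offset_max, intensity_offset_max)`, normalized units) and
#' additive Gaussian noise (default mean 0, sd 0.05).  The composition order
#' is fixed: crop, flips, intensity shift, noise.
#'
#' @param patch_size Patch edge length per axis (scalar or length-3), voxels.
#' @param flip_axes Integer subset of `1:3` (x, y, z); empty disables flips.
#' @param intensity_offset_max Maximum absolute intensity offset; 0 disables.
#' @param noise_mean,noise_sd Gaussian noise moments; `noise_sd = 0` disables.
#' @param foreground_bias Probability of forcing the patch to contain at
#'   least one foreground voxel.
#' @param random_crop If `FALSE`, take the deterministic center crop.
#' @param seed Integer RNG seed; augmentation is bit-reproducible per seed.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(patch_size = 96L, flip_axes = 1:3,
                                intensity_offset_max = 0.1,
                                noise_mean = 0, noise_sd = 0.05,
                                foreground_bias = 0.5, random_crop = TRUE,
                                seed = 1L) {
  patch_size <- rep_len(as.integer(patch_size), 3L)
  if (any(patch_size < 1L)) stop("patch_size must be positive", call. = FALSE)
  if (intensity_offset_max < 0 || noise_sd < 0)
    stop("augmentation magnitudes must be non-negative", call. = FALSE)
  structure(list(patch_size = patch_size,
                 flip_axes = as.integer(flip_axes),
                 intensity_offset_max = intensity_offset_max,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 foreground_bias = foreground_bias,
                 random_crop = isTRUE(random_crop), seed = as.integer(seed)),
            class = "augmentation_config")
}

# number of foreground voxels inside every patch-sized window, via a 3-D
# summed-area table; returns array over valid origins (dim - patch + 1)
window_foreground_counts <- function(fg, patch) {
  d <- dim(fg)
  cumsum_axis <- function(x, ax) {
    perm <- c(ax, setdiff(1:3, ax))
    y <- apply(x, setdiff(1:3, ax), cumsum)
    dim(y) <- d[perm]
    aperm(y, order(perm))
  }
  S <- fg * 1
  for (ax in 1:3) S <- cumsum_axis(S, ax)
  P <- array(0, d + 1L)
  P[-1, -1, -1] <- S
  n <- d - patch + 1L
  i0 <- seq_len(n[1]); j0 <- seq_len(n[2]); k0 <- seq_len(n[3])
  i1 <- i0 + patch[1]; j1 <- j0 + patch[2]; k1 <- k0 + patch[3]
  P[i1, j1, k1] - P[i0, j1, k1] - P[i1, j0, k1] - P[i1, j1, k0] +
    P[i0, j0, k1] + P[i0, j1, k0] + P[i1, j0, k0] - P[i0, j0, k0]
}

#' Apply training-time augmentation to an image/mask pair
#'
#' @param image A normalized [scalar_grid()] or 3-D array.
#' @param mask One-hot indicator stack from [one_hot()] sharing the image
#'   lattice.
#' @param config An [augmentation_config()].
#' @return List with elements `image` (3-D array patch) and `mask` (one-hot
#'   patch); flips are applied jointly, intensity shift and noise to the
#'   image only.
#' @export
augment <- function(image, mask, config) {
  stopifnot(inherits(config, "augmentation_config"))
  img <- if (inherits(image, "scalar_grid")) image$data else image
  d <- dim(img)
  if (!all(dim(mask)[1:3] == d))
    stop("image and mask must share a lattice", call. = FALSE)
  p <- config$patch_size
  if (any(p > d))
    stop("patch size (", paste(p, collapse = "x"),
         ") exceeds image size (", paste(d, collapse = "x"), ")",
         call. = FALSE)
  set.seed(config$seed)

  # crop
  if (config$random_crop) {
    nor <- d - p + 1L
    fg <- apply(mask[, , , -1, drop = FALSE], 1:3, max) > 0
    use_fg <- any(fg) && stats::runif(1) < config$foreground_bias
    if (use_fg) {
      counts <- window_foreground_counts(fg, p)
      cand <- which(counts > 0)
      pick <- cand[sample.int(length(cand), 1L)]
    } else {
      pick <- sample.int(prod(nor), 1L)
    }
    o <- arrayInd(pick, nor)[1, ]
  } else {
    o <- (d - p) %/% 2L + 1L
  }
  ix <- seq.int(o[1], length.out = p[1])
  iy <- seq.int(o[2], length.out = p[2])
  iz <- seq.int(o[3], length.out = p[3])
  img <- img[ix, iy, iz, drop = FALSE]
  msk <- mask[ix, iy, iz, , drop = FALSE]

  # flips, joint
  for (ax in config$flip_axes) {
    if (stats::runif(1) < 0.5) {
      img <- flip_array(img, ax)
      for (cl in seq_len(dim(msk)[4]))
        msk[, , , cl] <- flip_array(msk[, , , cl, drop = FALSE], ax)
    }
  }

  # intensity shift then Gaussian noise, image only
  if (config$intensity_offset_max > 0)
    img <- img + stats::runif(1, -config$intensity_offset_max,
                              config$intensity_offset_max)
  if (config$noise_sd > 0)
    img <- img + stats::rnorm(length(img), config$noise_mean, config$noise_sd)
  dim(img) <- p
  list(image = img, mask = msk)
}

#' Reverse an array along one axis
#' @param x 3-D (or 3-D + trailing singleton) array.
#' @param axis Axis index 1-3.
#' @return Array of the same shape.
#' @export
flip_array <- function(x, axis) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- rev(seq_len(d[axis]))
  out <- do.call(`[`, c(list(x), idx, drop = FALSE))
  dim(out) <- d
  out
}
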