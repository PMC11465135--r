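#' Scalar intensity grid
#'
#' A 3-D scalar lattice (Hounsfield units or normalized intensity) with its
#' world geometry: per-axis voxel spacing in mm, the world position of the
#' center of voxel (0,0,0), and an orthonormal direction matrix mapping index
#' axes to patient RAS axes (+x right, +y anterior, +z superior).  The world
#' coordinate of voxel (i,j,k) (0-based) is
#' `origin + direction %*% (spacing * c(i,j,k))`.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, voxel size per axis in mm; all > 0.
#' @param origin Numeric length-3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix (|det| = 1 within 1e-6).
#' @return An object of class `scalar_grid`.
#' @export
scalar_grid <- function(data, spacing, origin = c(0, 0, 0),
                        direction = diag(3)) {
  g <- structure(list(data = data, spacing = as.numeric(spacing),
                      origin = as.numeric(origin),
                      direction = unname(as.matrix(direction))),
                 class = "scalar_grid")
  validate_grid(g)
  g
}

#' Integer label grid
#'
#' A 3-D class map sharing [scalar_grid()] geometry.  Labels follow the fixed
#' coding 0 = background, 1 = right kidney, 2 = left kidney.
#'
#' @inheritParams scalar_grid
#' @param data 3-D array of integer labels in `{0, 1, 2}`.
#' @return An object of class `label_grid`.
#' @export
label_grid <- function(data, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  storage.mode(data) <- "integer"
  g <- structure(list(data = data, spacing = as.numeric(spacing),
                      origin = as.numeric(origin),
                      direction = unname(as.matrix(direction))),
                 class = c("label_grid", "scalar_grid"))
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  if (length(dim(g$data)) != 3L)
    stop("grid data must be a 3-D array", call. = FALSE)
  if (length(g$spacing) != 3L || any(!is.finite(g$spacing)) ||
      any(g$spacing <= 0))
    stop("spacing must be strictly positive on all three axes", call. = FALSE)
  if (length(g$origin) != 3L || any(!is.finite(g$origin)))
    stop("origin must be a finite length-3 vector", call. = FALSE)
  D <- g$direction
  if (!all(dim(D) == c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6 ||
      abs(abs(det(D)) - 1) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix", call. = FALSE)
  if (inherits(g, "label_grid")) {
    vals <- unique(as.vector(g$data))
    if (!all(vals %in% 0:2))
      stop("label values must be in {0, 1, 2} ",
           "(background, right kidney, left kidney)", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.scalar_grid <- function(x, ...) {
  kind <- if (inherits(x, "label_grid")) "label_grid" else "scalar_grid"
  cat(sprintf("<%s> %s voxels, spacing (%s) mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", ")))
  cat(sprintf("  origin (%s) mm\n",
              paste(format(x$origin, digits = 4), collapse = ", ")))
  if (inherits(x, "label_grid")) {
    tb <- table(factor(as.vector(x$data), levels = 0:2))
    cat(sprintf("  labels: bg %d, right %d, left %d\n", tb[1], tb[2], tb[3]))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Voxel-to-world affine of a grid
#'
#' @param grid A [scalar_grid()] or [label_grid()].
#' @return 4x4 affine matrix acting on 0-based voxel indices (homogeneous).
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  A[1:3, 1:3] <- grid$direction %*% diag(grid$spacing)
  A[1:3, 4] <- grid$origin
  A
}

#' World coordinates of voxel centers
#'
#' @param grid A grid object.
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices; default all
#'   voxels in column-major order.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
world_coords <- function(grid, ijk = NULL) {
  d <- dim(grid$data)
  if (is.null(ijk)) {
    ijk <- cbind(
      rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
      rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
      rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  }
  M <- grid$direction %*% diag(grid$spacing)
  sweep(ijk %*% t(M), 2, grid$origin, "+")
}

#' Test whether two grids share geometry
#'
#' @param a,b Grid objects.
#' @param tol Absolute tolerance (mm).
#' @return Logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

# replace the data payload, keeping geometry
with_data <- function(grid, data, label = inherits(grid, "label_grid")) {
  if (label)
    label_grid(data, grid$spacing, grid$origin, grid$direction)
  else
    scalar_grid(data, grid$spacing, grid$origin, grid$direction)
}

# intrinsic Euler rotations about x, y, z (degrees): R = Rz %*% Ry %*% Rx
#' Rotation matrix from Euler angles
#'
#' @param angles_deg Length-3 rotations about the x, y and z world axes in
#'   degrees, composed as `Rz %*% Ry %*% Rx`.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}
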