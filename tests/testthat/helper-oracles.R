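# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths.

# Brute-force two-way ANOVA ICC(3,1): sums of squares by direct summation.
oracle_icc3 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(x[i, ]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  msb <- ssb / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse)
}

# Brute-force Dice by explicit voxel loops over array indices.
oracle_dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# Digitized sphere mask (voxel centers, 0-based indices centered on the
# lattice midpoint).
sphere_mask <- function(radius, dim = rep(2 * radius + 9, 3), spacing = 1) {
  ctr <- (dim - 1) / 2
  xs <- (seq_len(dim[1]) - 1 - ctr[1]) * spacing
  ys <- (seq_len(dim[2]) - 1 - ctr[2]) * spacing
  zs <- (seq_len(dim[3]) - 1 - ctr[3]) * spacing
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  r2 <= radius^2
}

# Digitized axis-aligned ellipsoid at 1 mm spacing.
ellipsoid_mask <- function(semi, dim = 2 * ceiling(semi) + 9) {
  ctr <- (dim - 1) / 2
  xs <- ((seq_len(dim[1]) - 1 - ctr[1]) / semi[1])^2
  ys <- ((seq_len(dim[2]) - 1 - ctr[2]) / semi[2])^2
  zs <- ((seq_len(dim[3]) - 1 - ctr[3]) / semi[3])^2
  outer(outer(xs, ys, "+"), zs, "+") <= 1
}

# Wrap a binary array in a label_grid with a given class and spacing.
as_label <- function(bin, class_id = 1L, spacing = c(1, 1, 1),
                     origin = NULL) {
  d <- dim(bin)
  if (is.null(origin)) origin <- -(d - 1) * spacing / 2
  label_grid(array(as.integer(bin) * class_id, d), spacing, origin)
}
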