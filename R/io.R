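#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` volume and reorients it to the canonical RAS+
#' frame (+x patient right, +y anterior, +z superior) so that downstream
#' anatomical axis labeling operates in a fixed frame.  Intensities are
#' returned unchanged.
#'
#' @param path Path to a NIfTI file.
#' @return A [scalar_grid()] in canonical RAS+ orientation.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unreadable volume '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)), " dimensions",
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("missing or invalid voxel spacing metadata in '", path,
         "'; refusing to assume 1 mm", call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  nifti_to_grid(img)
}

#' Read a label map from NIfTI
#'
#' As [read_volume()] but validates and returns a [label_grid()] with the
#' fixed class coding 0/1/2 = background/right kidney/left kidney.
#'
#' @inheritParams read_volume
#' @return A [label_grid()] in canonical RAS+ orientation.
#' @export
read_labelmap <- function(path) {
  g <- read_volume(path)
  data <- round(g$data)
  if (max(abs(data - g$data)) > 1e-6)
    stop("label map contains non-integer values", call. = FALSE)
  label_grid(data, g$spacing, g$origin, g$direction)
}

nifti_to_grid <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  direction <- aff[1:3, 1:3] %*% diag(1 / spacing)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))  # drop niftiImage attributes
  scalar_grid(data, spacing, aff[1:3, 4], direction)
}

grid_to_nifti <- function(grid) {
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  aff <- grid_affine(grid)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  img
}

#' Write a volume to NIfTI
#'
#' @param grid A [scalar_grid()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  validate_grid(grid)
  RNifti::writeNifti(grid_to_nifti(grid), path)
  invisible(path)
}

#' Write a label map to NIfTI
#'
#' Label invariants (values in `{0,1,2}`) are enforced before writing; the
#' written file round-trips through [read_labelmap()] with identical voxel
#' data and geometry.
#'
#' @param mask A [label_grid()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(mask, path) {
  if (!inherits(mask, "label_grid"))
    stop("mask must be a label_grid", call. = FALSE)
  validate_grid(mask)
  RNifti::writeNifti(grid_to_nifti(mask), path, datatype = "uint8")
  invisible(path)
}
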