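#' CT volume
#'
#' A 3D grid of Hounsfield-unit (HU) voxel values with per-axis spacing in
#' millimetres. The axis convention throughout the package is
#' (x = left-right, y = anterior-posterior, z = inferior-superior); the
#' left-right mirror used for laterality flips reverses the first axis.
#'
#' @param voxels 3D numeric array of HU values; all values must be finite.
#' @param spacing Numeric length-3 vector, mm per voxel along each axis.
#' @return An object of class `ct_volume` with fields `voxels` and `spacing`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2.5))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort_validation("`voxels` must be a 3D array.")
  }
  if (!all(is.finite(voxels))) {
    abort_validation("CT volume contains non-finite voxel values.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_validation("`spacing` must be 3 strictly positive numbers (mm).")
  }
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' Validate a binary mask array
#'
#' Masks are plain 3D arrays restricted to values {0, 1}. Stored as integer.
#'
#' @param voxels 3D array with values 0/1 (or logical).
#' @param shape Optional expected dim to check against.
#' @return The validated mask as a 3D integer array.
#' @export
binary_mask <- function(voxels, shape = NULL) {
  if (is.logical(voxels)) {
    storage.mode(voxels) <- "integer"
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort_validation("A binary mask must be a 3D array.")
  }
  if (!all(voxels %in% c(0L, 1L))) {
    abort_validation("Mask values must be 0 or 1.")
  }
  if (!is.null(shape) && !identical(dim(voxels), as.integer(shape))) {
    abort_format(sprintf(
      "Mask shape (%s) does not match expected shape (%s).",
      paste(dim(voxels), collapse = "x"), paste(shape, collapse = "x")
    ))
  }
  storage.mode(voxels) <- "integer"
  voxels
}

mask_count <- function(mask) sum(mask != 0)

# 1-based foreground voxel coordinates, n x 3 matrix
mask_coords <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}
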