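#' Soft confusion counts between a prediction and a reference
#'
#' For a binary prediction these are the usual true-positive, false-positive
#' and false-negative voxel counts; for a soft (probability-valued)
#' prediction the counts are replaced by sums of probabilities, so the same
#' formula yields the soft Dice used during training.
#'
#' @param pred 3D array, binary or probabilities in `[0, 1]`.
#' @param ref 3D array with values 0/1.
#' @return A list with fields `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) {
    abort_format("Prediction and reference shapes differ.")
  }
  p <- as.numeric(pred)
  r <- as.numeric(ref)
  list(
    tp = sum(p * r),
    fp = sum(p * (1 - r)),
    fn = sum((1 - p) * r)
  )
}

#' Sorensen-Dice coefficient
#'
#' `SDC = 2 tp / (2 tp + fp + fn)`, the standard overlap metric between a
#' predicted and a reference voxel set. Accepts a soft prediction, in which
#' case the counts are sums of probabilities. When both masks are empty the
#' coefficient is defined as 1 (perfect agreement on absence) and the result
#' carries the attribute `both_empty = TRUE` as a flag.
#'
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @examples
#' a <- array(0L, c(3, 3, 1)); a[1:2, 1, 1] <- 1L
#' sdc(a, a) # 1
#' @export
sdc <- function(pred, ref) {
  weighted_sdc(pred, ref, w = 1)
}

#' True-positive-weighted Sorensen-Dice coefficient
#'
#' `SDC(w) = 2 w tp / (2 w tp + fp + fn)`. Down-weighting the true-positive
#' term (`w` = 0.5 or 0.05) increases the relative influence of surface
#' errors, which is the motivation for using it as a training cost. `w = 1`
#' recovers the plain coefficient, and a perfect prediction still scores 1.
#'
#' @inheritParams confusion_counts
#' @param w Positive true-positive weight.
#' @return A number in `[0, 1]`.
#' @export
weighted_sdc <- function(pred, ref, w = 1) {
  if (w <= 0) abort_validation("`w` must be > 0.")
  cc <- confusion_counts(pred, ref)
  denom <- 2 * w * cc$tp + cc$fp + cc$fn
  if (denom == 0) {
    return(structure(1.0, both_empty = TRUE))
  }
  2 * w * cc$tp / denom
}

#' 3D Hausdorff distance between two masks
#'
#' The symmetric Hausdorff distance: the larger of the two directed
#' maximum-minimum Euclidean distances between foreground voxel centres.
#' Computed in voxel-index space by default; pass `spacing` to measure in mm.
#'
#' @param a,b 3D arrays with values 0/1, both non-empty.
#' @param spacing Optional length-3 mm-per-voxel scaling.
#' @return Distance `>= 0` (voxel-index units, or mm with `spacing`).
#' @export
hausdorff_3d <- function(a, b, spacing = NULL) {
  ca <- mask_coords(a)
  cb <- mask_coords(b)
  if (nrow(ca) == 0 || nrow(cb) == 0) {
    empty_side <- if (nrow(ca) == 0) "first" else "second"
    abort_metric(
      sprintf("Hausdorff distance undefined: %s mask is empty.", empty_side),
      empty_side = empty_side
    )
  }
  ca <- matrix(as.numeric(ca), ncol = 3)
  cb <- matrix(as.numeric(cb), ncol = 3)
  if (!is.null(spacing)) {
    ca <- sweep(ca, 2, spacing, `*`)
    cb <- sweep(cb, 2, spacing, `*`)
  }
  max(cpp_hausdorff_directed(ca, cb), cpp_hausdorff_directed(cb, ca))
}

# Marching-squares perimeter of one binary slice at iso-level 0.5. With
# binary data every crossing sits at an edge midpoint, so each 2x2 cell
# contributes a fixed segment length by case; the diagonal (ambiguous)
# cases contribute two corner cuts.
ms_perimeter <- function(slice) {
  b <- matrix(0L, nrow(slice) + 2L, ncol(slice) + 2L)
  b[2:(nrow(slice) + 1L), 2:(ncol(slice) + 1L)] <- (slice != 0) * 1L
  nr <- nrow(b); nc <- ncol(b)
  tl <- b[-nr, -nc]; tr <- b[-1, -nc]; bl <- b[-nr, -1]; br <- b[-1, -1]
  code <- tl + 2L * tr + 4L * br + 8L * bl
  half_diag <- sqrt(0.5)
  # lengths per case 0..15
  len <- c(
    0, half_diag, half_diag, 1, half_diag, 2 * half_diag, 1, half_diag,
    half_diag, 1, 2 * half_diag, half_diag, 1, half_diag, half_diag, 0
  )
  counts <- tabulate(code + 1L, nbins = 16L)
  sum(counts * len)
}

#' Contour complexity of a mask
#'
#' For every axial (third-axis) slice with foreground, the contour length
#' (sub-pixel marching-squares perimeter at iso-level 0.5) is divided by the
#' foreground area, and the per-slice ratios are averaged. Lower values
#' indicate smoother contours: a disk of radius r scores about 2/r, and
#' scaling a shape up in-plane by a factor s divides the score by s.
#'
#' @param mask 3D array with values 0/1, non-empty.
#' @return Mean perimeter-to-area ratio, `>= 0`.
#' @export
contour_complexity <- function(mask) {
  if (mask_count(mask) == 0) {
    abort_metric("Contour complexity undefined for an empty mask.")
  }
  nz <- dim(mask)[3]
  ratios <- vapply(seq_len(nz), function(k) {
    sl <- mask[, , k]
    area <- sum(sl != 0)
    if (area == 0) {
      return(NA_real_)
    }
    ms_perimeter(sl) / area
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}
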