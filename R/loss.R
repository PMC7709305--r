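#' Training-cost specification
#'
#' Selects the training cost: plain soft Dice (`"sdc"`), true-positive
#' weighted soft Dice (`"sdc_weighted"`, `w` typically 0.5 or 0.05), or the
#' combined Dice-plus-Hausdorff cost (`"sdc_plus_hd"`), in which the
#' Hausdorff term is normalised by `0.33 * x` with `x` the region-of-interest
#' diagonal — the maximum possible Hausdorff distance on the crop grid.
#'
#' The combined cost is minimised, so the Dice contribution enters as
#' `1 - softSDC` by default; set `use_negative_sdc = TRUE` for `-softSDC`
#' instead (both are minimised where the coefficient is maximised).
#'
#' @param kind `"sdc"`, `"sdc_weighted"` or `"sdc_plus_hd"`.
#' @param w Positive true-positive weight (1, 0.5 or 0.05 in the standard
#'   comparisons).
#' @param roi_diagonal ROI diagonal in voxels; required for `"sdc_plus_hd"`.
#' @param use_negative_sdc Use `-softSDC` instead of `1 - softSDC` as the
#'   Dice contribution of the combined cost.
#' @param epsilon Optional smoothing added to the soft-Dice denominator for
#'   empty-reference batches; 0 by default.
#' @return An object of class `loss_spec` with the derived field
#'   `hd_normalizer = 0.33 * roi_diagonal` when applicable.
#' @examples
#' loss_spec("sdc_plus_hd", roi_diagonal = roi_diagonal(c(64, 64, 32)))
#' @export
loss_spec <- function(kind = c("sdc", "sdc_weighted", "sdc_plus_hd"), w = 1,
                      roi_diagonal = NULL, use_negative_sdc = FALSE,
                      epsilon = 0) {
  kind <- match.arg(kind)
  if (w <= 0) abort_validation("`w` must be > 0.")
  if (kind == "sdc_plus_hd") {
    if (is.null(roi_diagonal) || roi_diagonal <= 0) {
      abort_validation("`sdc_plus_hd` requires a positive `roi_diagonal`.")
    }
  }
  structure(
    list(
      kind = kind, w = w, roi_diagonal = roi_diagonal,
      hd_normalizer = if (!is.null(roi_diagonal)) 0.33 * roi_diagonal,
      use_negative_sdc = use_negative_sdc, epsilon = epsilon
    ),
    class = "loss_spec"
  )
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf(
    "<loss_spec> %s  w=%g%s\n", x$kind, x$w,
    if (!is.null(x$roi_diagonal)) {
      sprintf("  roi_diagonal=%g (HD normalizer %.4g)", x$roi_diagonal, x$hd_normalizer)
    } else ""
  ))
  invisible(x)
}

#' Region-of-interest diagonal
#'
#' The Euclidean diagonal of a crop grid in voxels — the maximum possible
#' Hausdorff distance between two masks on that grid, used to normalise the
#' Hausdorff term of the combined cost.
#'
#' @param crop_shape Integer length-3 crop extent.
#' @return `sqrt(sum(crop_shape^2))`.
#' @examples
#' roi_diagonal(c(64, 64, 32)) # 96
#' @export
roi_diagonal <- function(crop_shape) {
  sqrt(sum(as.numeric(crop_shape)^2))
}

# Soft weighted Dice loss with analytic gradient wrt the probabilities.
# Returns list(value, grad); value = 1 - softSDC(w) (or -softSDC).
dice_loss_grad <- function(p, r, w = 1, negative = FALSE, epsilon = 0) {
  p <- as.numeric(p)
  r <- as.numeric(r)
  tp <- sum(p * r)
  fp <- sum(p * (1 - r))
  fn <- sum((1 - p) * r)
  denom <- 2 * w * tp + fp + fn + epsilon
  if (denom == 0) {
    return(list(value = if (negative) -1 else 0, grad = numeric(length(p))))
  }
  s <- 2 * w * tp / denom
  # dS/dp_i = (2 w r_i * denom - 2 w tp * (2 w r_i + 1 - 2 r_i)) / denom^2
  ds <- (2 * w * r * denom - 2 * w * tp * (2 * w * r + 1 - 2 * r)) / denom^2
  if (negative) {
    list(value = -s, grad = -ds)
  } else {
    list(value = 1 - s, grad = -ds)
  }
}

#' Soft Dice training loss
#'
#' `1 - softSDC(w)` (or `-softSDC(w)`), where the soft coefficient replaces
#' voxel counts by sums of predicted probabilities. This is the
#' differentiable part of every training cost in the package.
#'
#' @param pred_soft 3D array of probabilities in `[0, 1]`.
#' @param ref 3D array with values 0/1.
#' @param spec A [loss_spec()] of kind `"sdc"` or `"sdc_weighted"`.
#' @return The loss value.
#' @export
dice_loss <- function(pred_soft, ref, spec = loss_spec("sdc")) {
  if (!identical(dim(pred_soft), dim(ref))) {
    abort_format("Prediction and reference shapes differ.")
  }
  dice_loss_grad(
    pred_soft, ref,
    w = spec$w, negative = spec$use_negative_sdc,
    epsilon = spec$epsilon
  )$value
}

#' Combined Dice + Hausdorff training cost
#'
#' `cost = dice_term + HD / (0.33 x)`, where the Hausdorff distance is
#' computed between the 0.5-binarised prediction and the reference, and `x`
#' is the ROI diagonal (the maximum possible HD), so the normalised term
#' lies in `[0, 1/0.33]`. The Hausdorff term is a non-differentiable
#' penalty: during training the gradient flows only through the Dice term.
#' An empty binarised prediction receives the maximal Hausdorff term
#' `1/0.33`, flagged via the attribute `empty_pred`.
#'
#' @param pred_soft 3D array of probabilities.
#' @param ref 3D binary reference mask.
#' @param spec A [loss_spec()] of kind `"sdc_plus_hd"`.
#' @return The cost value; attribute `empty_pred = TRUE` when the binarised
#'   prediction was empty.
#' @export
combined_loss <- function(pred_soft, ref, spec) {
  if (!inherits(spec, "loss_spec") || spec$kind != "sdc_plus_hd") {
    abort_validation("`spec` must be a loss_spec of kind 'sdc_plus_hd'.")
  }
  if (!identical(dim(pred_soft), dim(ref))) {
    abort_format("Prediction and reference shapes differ.")
  }
  dice_term <- dice_loss_grad(
    pred_soft, ref,
    w = spec$w, negative = spec$use_negative_sdc, epsilon = spec$epsilon
  )$value
  bin <- (pred_soft >= 0.5) * 1L
  dim(bin) <- dim(pred_soft)
  if (sum(bin) == 0) {
    hd_term <- 1 / 0.33
    return(structure(dice_term + hd_term, empty_pred = TRUE))
  }
  hd <- hausdorff_3d(bin, ref)
  dice_term + hd / spec$hd_normalizer
}

# Training-time loss evaluation: value + gradient wrt probabilities for any
# loss_spec kind. The HD penalty contributes to the value only.
loss_value_grad <- function(p, r, spec) {
  out <- dice_loss_grad(
    p, r,
    w = spec$w, negative = spec$use_negative_sdc, epsilon = spec$epsilon
  )
  if (spec$kind == "sdc_plus_hd") {
    bin <- (p >= 0.5) * 1L
    dim(bin) <- dim(p)
    rdim <- dim(r) %||% dim(p)
    rr <- r
    dim(rr) <- rdim
    hd_term <- if (sum(bin) == 0) {
      1 / 0.33
    } else {
      hausdorff_3d(bin, rr) / spec$hd_normalizer
    }
    out$value <- out$value + hd_term
  }
  out
}
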