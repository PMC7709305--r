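#' Hounsfield-unit window
#'
#' A clipping range for HU values given as centre/width, with derived bounds
#' `lower = center - width/2` and `upper = center + width/2`. Windowing
#' removes extreme values (bone, air) and stretches soft-tissue contrast.
#'
#' @param center Window centre in HU.
#' @param width Window width in HU, strictly positive.
#' @return An object of class `hu_window` with fields `center`, `width`,
#'   `lower`, `upper`.
#' @examples
#' hu_window(50, 250)           # the default submandibular window (-75, 175)
#' hu_window_bounds(-190, 310)  # the default parotid window
#' @export
hu_window <- function(center, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort_validation("Window `width` must be a single positive number (HU).")
  }
  structure(
    list(
      center = as.numeric(center), width = as.numeric(width),
      lower = as.numeric(center - width / 2),
      upper = as.numeric(center + width / 2)
    ),
    class = "hu_window"
  )
}

#' @rdname hu_window
#' @param lower,upper Window bounds in HU, `lower < upper`.
#' @export
hu_window_bounds <- function(lower, upper) {
  if (upper <= lower) {
    abort_validation("Window must satisfy lower < upper.")
  }
  hu_window(center = (lower + upper) / 2, width = upper - lower)
}

#' @export
print.hu_window <- function(x, ...) {
  cat(sprintf(
    "<hu_window> center %g, width %g  (HU range [%g, %g])\n",
    x$center, x$width, x$lower, x$upper
  ))
  invisible(x)
}

default_hu_window <- function(organ) {
  switch(organ,
    SMG = hu_window_bounds(-75, 175),
    PG = hu_window_bounds(-190, 310),
    abort_validation("Unknown organ.")
  )
}

default_crop_shape <- function(organ) {
  switch(organ,
    SMG = c(64L, 64L, 32L),
    PG = c(96L, 64L, 64L),
    abort_validation("Unknown organ.")
  )
}

#' Region-of-interest specification
#'
#' Bundles the organ-specific crop shape and HU window used by the base
#' preprocessing chain. Defaults follow the organ: a 64 x 64 x 32 voxel crop
#' with window (-75, 175) HU for the submandibular gland, and 96 x 64 x 64
#' with (-190, 310) HU for the parotid.
#'
#' @param organ `"SMG"` or `"PG"`.
#' @param crop_shape Integer length-3 crop extent in voxels; `NULL` for the
#'   organ default.
#' @param window A [hu_window()]; `NULL` for the organ default.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(organ = c("SMG", "PG"), crop_shape = NULL, window = NULL) {
  organ <- match.arg(organ)
  if (is.null(crop_shape)) crop_shape <- default_crop_shape(organ)
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3 || any(crop_shape < 1)) {
    abort_validation("`crop_shape` must be 3 positive integers.")
  }
  if (is.null(window)) window <- default_hu_window(organ)
  if (!inherits(window, "hu_window")) {
    abort_validation("`window` must be an hu_window.")
  }
  structure(
    list(organ = organ, crop_shape = crop_shape, window = window),
    class = "roi_spec"
  )
}

#' Read a region-of-interest specification from YAML
#'
#' Recognised keys: `organ`, `crop_shape` (3 integers), `hu_window` with
#' either `center`/`width` or `lower`/`upper`.
#'
#' @param path Path to a YAML file.
#' @return A [roi_spec()].
#' @export
roi_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  win <- NULL
  if (!is.null(cfg$hu_window)) {
    w <- cfg$hu_window
    win <- if (!is.null(w$center)) {
      hu_window(w$center, w$width)
    } else {
      hu_window_bounds(w$lower, w$upper)
    }
  }
  roi_spec(
    organ = toupper(cfg$organ %||% "SMG"),
    crop_shape = cfg$crop_shape, window = win
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a fixed-shape region of interest centred on the organ
#'
#' The crop centre is the organ-mask centroid rounded to the nearest voxel,
#' which makes the crop deterministic and translation-equivariant. Regions
#' extending past the volume boundary are padded with the window's lower HU
#' bound for the image and 0 for the masks. If the organ's bounding box
#' exceeds the crop shape along any axis a warning is raised but the crop is
#' still produced.
#'
#' @param case A [seg_case()].
#' @param spec A [roi_spec()].
#' @return A [seg_case()] whose arrays have shape `spec$crop_shape`.
#' @export
crop_roi <- function(case, spec) {
  validate_seg_case(case)
  d <- dim(case$image$voxels)
  s <- spec$crop_shape
  coords <- mask_coords(case$organ_mask)
  centroid <- round(colMeans(coords))
  extent <- apply(coords, 2, function(v) diff(range(v)) + 1L)
  if (any(extent > s)) {
    warn(
      sprintf(
        "Organ extent (%s) exceeds crop shape (%s); organ will be truncated.",
        paste(extent, collapse = "x"), paste(s, collapse = "x")
      ),
      class = "oarseg_warning_crop"
    )
  }
  pad_hu <- spec$window$lower
  idx <- lapply(1:3, function(ax) {
    start <- centroid[ax] - floor(s[ax] / 2)
    seq.int(start, length.out = s[ax])
  })
  take <- function(arr, fill) {
    out <- array(fill, dim = s)
    valid <- lapply(1:3, function(ax) idx[[ax]] >= 1 & idx[[ax]] <= d[ax])
    out[valid[[1]], valid[[2]], valid[[3]]] <-
      arr[
        idx[[1]][valid[[1]]], idx[[2]][valid[[2]]], idx[[3]][valid[[3]]],
        drop = FALSE
      ]
    out
  }
  case$image$voxels <- take(case$image$voxels, pad_hu)
  case$organ_mask <- binary_mask(take(case$organ_mask, 0L))
  case$body_mask <- binary_mask(take(case$body_mask, 0L))
  case
}

#' Clip a volume into an HU window
#'
#' Every voxel is clipped into `[lower, upper]`; values already inside the
#' window are unchanged. Idempotent.
#'
#' @param volume A [ct_volume()].
#' @param window A [hu_window()].
#' @return The windowed [ct_volume()].
#' @export
apply_hu_window <- function(volume, window) {
  volume$voxels[] <- pmin(pmax(volume$voxels, window$lower), window$upper)
  volume
}

#' Normalise a windowed volume to zero-mean `[0, 1]` scale
#'
#' Applies the affine map sending `window$lower` to 0 and `window$upper` to
#' 1, then subtracts the volume mean so the data are centred around 0. The
#' divisor is the fixed window width rather than the per-volume range, which
#' keeps the map deterministic for degenerate (e.g. constant) volumes.
#'
#' @param volume A [ct_volume()], already clipped with `window`.
#' @param window The [hu_window()] used for clipping.
#' @return The normalised [ct_volume()] (values no longer in HU).
#' @export
normalize_volume <- function(volume, window) {
  v <- (volume$voxels - window$lower) / window$width
  volume$voxels <- v - mean(v)
  volume
}

#' Base preprocessing chain: crop, window, normalise
#'
#' The composition [crop_roi()], [apply_hu_window()], [normalize_volume()],
#' with the masks cropped consistently. This is the standard input pipeline
#' in front of the segmentation model.
#'
#' @param case A [seg_case()].
#' @param spec A [roi_spec()].
#' @return A [seg_case()] on the crop grid with a normalised image. The
#'   attribute `"preprocessed"` records the spec used.
#' @export
preprocess_case <- function(case, spec) {
  out <- crop_roi(case, spec)
  out$image <- apply_hu_window(out$image, spec$window)
  out$image <- normalize_volume(out$image, spec$window)
  attr(out, "preprocessed") <- spec
  out
}
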