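#' Segmentation case
#'
#' The unit of training and evaluation: a CT volume paired with a binary
#' organ mask (the reference contour), a binary body mask (the outer body
#' contour), the organ label and the laterality of the gland.
#'
#' Invariants: the organ mask is non-empty and every organ voxel is also a
#' body voxel; all three arrays share one grid shape.
#'
#' @param image A [ct_volume()].
#' @param organ_mask,body_mask 3D arrays with values 0/1.
#' @param organ `"SMG"` (submandibular) or `"PG"` (parotid).
#' @param laterality `"left"` or `"right"`.
#' @param case_id Opaque identifier string.
#' @return An object of class `seg_case`.
#' @export
seg_case <- function(image, organ_mask, body_mask,
                     organ = c("SMG", "PG"),
                     laterality = c("left", "right"),
                     case_id = "case") {
  organ <- match.arg(organ)
  laterality <- match.arg(laterality)
  if (!inherits(image, "ct_volume")) {
    abort_validation("`image` must be a ct_volume.")
  }
  organ_mask <- binary_mask(organ_mask, shape = dim(image$voxels))
  body_mask <- binary_mask(body_mask, shape = dim(image$voxels))
  case <- structure(
    list(
      image = image, organ_mask = organ_mask, body_mask = body_mask,
      organ = organ, laterality = laterality, case_id = as.character(case_id)
    ),
    class = "seg_case"
  )
  validate_seg_case(case)
}

#' Check seg_case invariants
#'
#' @param case A [seg_case()].
#' @return The case, invisibly usable in pipelines; errors on violation.
#' @export
validate_seg_case <- function(case) {
  if (!inherits(case, "seg_case")) {
    abort_validation("Not a seg_case.")
  }
  d <- dim(case$image$voxels)
  if (!identical(dim(case$organ_mask), d) || !identical(dim(case$body_mask), d)) {
    abort_format("Image and mask grid shapes differ.")
  }
  if (mask_count(case$organ_mask) == 0) {
    abort_validation("Organ mask is empty.")
  }
  if (any(case$organ_mask == 1L & case$body_mask == 0L)) {
    abort_validation("Organ mask is not a subset of the body mask.")
  }
  case
}

#' @export
print.seg_case <- function(x, ...) {
  d <- dim(x$image$voxels)
  cat(sprintf(
    "<seg_case> %s  organ=%s (%s)  grid %dx%dx%d  organ voxels=%d\n",
    x$case_id, x$organ, x$laterality, d[1], d[2], d[3],
    mask_count(x$organ_mask)
  ))
  invisible(x)
}

#' Read a case from NIfTI files
#'
#' Reads the image and both masks from NIfTI (`.nii`/`.nii.gz`) files, takes
#' the voxel spacing from the image header, and verifies all case invariants
#' (matching grids, binary masks, non-empty organ mask inside the body mask).
#'
#' @param image_path,organ_mask_path,body_mask_path Paths to NIfTI files on
#'   an identical grid.
#' @inheritParams seg_case
#' @return A [seg_case()].
#' @export
read_case <- function(image_path, organ_mask_path, body_mask_path,
                      organ = c("SMG", "PG"), laterality = c("left", "right"),
                      case_id = NULL) {
  img <- RNifti::readNifti(image_path)
  om <- RNifti::readNifti(organ_mask_path)
  bm <- RNifti::readNifti(body_mask_path)
  if (!identical(dim(img)[1:3], dim(om)[1:3]) ||
      !identical(dim(img)[1:3], dim(bm)[1:3])) {
    abort_format("NIfTI grids of image and masks do not match.")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(case_id)) {
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  }
  seg_case(
    image = ct_volume(array(as.numeric(img), dim(img)[1:3]), spacing = spacing),
    organ_mask = array(as.integer(round(as.numeric(om))), dim(om)[1:3]),
    body_mask = array(as.integer(round(as.numeric(bm))), dim(bm)[1:3]),
    organ = organ, laterality = laterality, case_id = case_id
  )
}

#' Write a case to NIfTI files
#'
#' Image voxels are written as 32-bit float; masks as unsigned 8-bit with
#' values {0, 1}. Spacing is stored in the headers.
#'
#' @param case A [seg_case()].
#' @param image_path,organ_mask_path,body_mask_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_case <- function(case, image_path, organ_mask_path, body_mask_path) {
  validate_seg_case(case)
  write_one <- function(arr, path, datatype) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- case$image$spacing
    RNifti::writeNifti(im, path, datatype = datatype)
  }
  write_one(case$image$voxels, image_path, "double")
  write_one(case$organ_mask, organ_mask_path, "uint8")
  write_one(case$body_mask, body_mask_path, "uint8")
  invisible(c(image_path, organ_mask_path, body_mask_path))
}

#' Mirror a case across the left-right axis
#'
#' Flips the image and both masks along the first (left-right) axis and
#' toggles the recorded laterality. Used to pool left and right glands under
#' a symmetry assumption. The operation is an exact involution.
#'
#' @param case A [seg_case()].
#' @return The mirrored [seg_case()].
#' @export
flip_lateral <- function(case) {
  validate_seg_case(case)
  nx <- dim(case$image$voxels)[1]
  rev1 <- function(a) a[nx:1, , , drop = FALSE]
  case$image$voxels <- rev1(case$image$voxels)
  case$organ_mask <- rev1(case$organ_mask)
  case$body_mask <- rev1(case$body_mask)
  case$laterality <- if (case$laterality == "left") "right" else "left"
  case
}
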