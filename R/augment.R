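#' Traditional augmentation parameters
#'
#' Controls the generic image-transform augmentations: left-right flip,
#' rotation about all three axes, and additive Gaussian HU noise with
#' standard deviation `noise_sigma` (default 15 HU). Each enabled operation
#' fires independently with probability `p_apply`; if none fires, the draw
#' is repeated so an augmented copy always differs from its source.
#'
#' @param noise_sigma Noise SD in HU (>= 0).
#' @param enable_flip,enable_rotation,enable_noise Logical switches.
#' @param p_apply Per-operation application probability in `[0, 1]`.
#' @param in_plane_rotation If `TRUE`, rotate only about the z axis.
#' @return An object of class `traditional_aug_params`.
#' @export
traditional_aug_params <- function(noise_sigma = 15, enable_flip = TRUE,
                                   enable_rotation = TRUE, enable_noise = TRUE,
                                   p_apply = 0.5, in_plane_rotation = FALSE) {
  if (noise_sigma < 0) abort_validation("`noise_sigma` must be >= 0.")
  if (p_apply < 0 || p_apply > 1) abort_validation("`p_apply` must be in [0,1].")
  structure(
    list(
      noise_sigma = noise_sigma, enable_flip = enable_flip,
      enable_rotation = enable_rotation, enable_noise = enable_noise,
      p_apply = p_apply, in_plane_rotation = in_plane_rotation
    ),
    class = "traditional_aug_params"
  )
}

#' Domain-specific augmentation parameters
#'
#' Parameters of the CT-plausible augmentation: elastic deformation
#' (displacement scale `elastic_alpha` voxels, smoothing width
#' `elastic_sigma` voxels, affine jitter scale `affine_alpha`) plus additive
#' HU density shifts of the whole body (`body_shift_sigma`, default 100 HU)
#' and of the organ (`oar_shift_sigma`, default 30 HU). Organ defaults are
#' alpha 38 / sigma 3.8 / affine 3.8 for the submandibular gland and
#' 58 / 5.8 / 5.8 for the parotid.
#'
#' @param organ `"SMG"` or `"PG"`, sets the elastic defaults.
#' @param elastic_alpha,elastic_sigma,affine_alpha Elastic-field parameters
#'   (voxels); `NULL` for the organ default.
#' @param body_shift_sigma,oar_shift_sigma Density-shift SDs in HU.
#' @return An object of class `domain_aug_params`.
#' @export
domain_aug_params <- function(organ = c("SMG", "PG"), elastic_alpha = NULL,
                              elastic_sigma = NULL, affine_alpha = NULL,
                              body_shift_sigma = 100, oar_shift_sigma = 30) {
  organ <- match.arg(organ)
  defaults <- switch(organ,
    SMG = c(38, 3.8, 3.8),
    PG = c(58, 5.8, 5.8)
  )
  p <- list(
    organ = organ,
    elastic_alpha = elastic_alpha %||% defaults[1],
    elastic_sigma = elastic_sigma %||% defaults[2],
    affine_alpha = affine_alpha %||% defaults[3],
    body_shift_sigma = body_shift_sigma,
    oar_shift_sigma = oar_shift_sigma
  )
  vals <- unlist(p[-1])
  if (any(vals < 0)) abort_validation("All scales and sigmas must be >= 0.")
  structure(p, class = "domain_aug_params")
}

#' Add Gaussian HU noise
#'
#' Adds independent N(0, sigma^2) noise to every voxel. Deterministic given
#' the stream's seed; `sigma = 0` is an exact identity.
#'
#' @param volume A [ct_volume()].
#' @param sigma Noise standard deviation in HU.
#' @param rng An [rng_stream()] or `NULL`.
#' @return The noisy [ct_volume()].
#' @export
add_gaussian_noise <- function(volume, sigma = 15, rng = NULL) {
  if (sigma < 0) abort_validation("`sigma` must be >= 0.")
  if (sigma == 0) {
    return(volume)
  }
  n <- length(volume$voxels)
  volume$voxels <- volume$voxels + array(
    with_rng(rng, rnorm(n, 0, sigma)),
    dim = dim(volume$voxels)
  )
  volume
}

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

warp_case <- function(case, A, shift = c(0, 0, 0), disp = NULL, fill = NULL) {
  d <- dim(case$image$voxels)
  if (is.null(fill)) fill <- min(case$image$voxels)
  # backward warp: sample the source at A %*% (p - c) + c + shift + disp,
  # so the voxel-space transform applied to content is the inverse of A
  case$image$voxels <- array(
    cpp_warp(case$image$voxels, d, A, shift, disp, FALSE, fill),
    dim = d
  )
  warp_mask <- function(m) {
    binary_mask(array(
      as.integer(cpp_warp(as.numeric(m), d, A, shift, disp, TRUE, 0)),
      dim = d
    ))
  }
  case$organ_mask <- warp_mask(case$organ_mask)
  case$body_mask <- warp_mask(case$body_mask)
  case
}

#' Random 3D rotation
#'
#' Rotates image and masks by one shared random rotation, with Euler angles
#' drawn uniformly on `[0, 360)` degrees per axis (or about z only when
#' `in_plane = TRUE`). The image is interpolated trilinearly; masks use
#' nearest-neighbour so they stay binary. Regions rotated in from outside
#' the grid are filled with `fill` for the image (the volume minimum, i.e.
#' air-like, when `NULL`) and 0 for the masks.
#'
#' @param case A [seg_case()].
#' @param rng An [rng_stream()] or `NULL`.
#' @param angles Optional fixed Euler angles in degrees (length 3),
#'   overriding the random draw.
#' @param in_plane Rotate only about the z (slice) axis.
#' @param fill Image fill value in HU, or `NULL` for the volume minimum.
#' @return The rotated [seg_case()].
#' @export
random_rotate <- function(case, rng = NULL, angles = NULL, in_plane = FALSE,
                          fill = NULL) {
  validate_seg_case(case)
  if (is.null(angles)) {
    angles <- with_rng(rng, runif(3, 0, 360))
    if (in_plane) angles[1:2] <- 0
  }
  warp_case(case, rotation_matrix(angles), fill = fill)
}

#' Traditional augmentation of one case
#'
#' Applies each enabled operation (flip, rotation, noise) independently with
#' its application probability; if no operation fires the draw is repeated.
#'
#' @param case A [seg_case()].
#' @param params A [traditional_aug_params()].
#' @param rng An [rng_stream()] or `NULL`.
#' @return The augmented [seg_case()].
#' @export
traditional_augment <- function(case, params = traditional_aug_params(),
                                rng = NULL) {
  validate_seg_case(case)
  enabled <- c(params$enable_flip, params$enable_rotation, params$enable_noise)
  if (!any(enabled)) {
    abort_validation("At least one traditional operation must be enabled.")
  }
  fire <- with_rng(rng, {
    repeat {
      f <- enabled & (runif(3) < params$p_apply)
      if (any(f)) break
    }
    f
  })
  out <- case
  if (fire[1]) out <- flip_lateral(out)
  if (fire[2]) out <- random_rotate(out, rng, in_plane = params$in_plane_rotation)
  if (fire[3]) out$image <- add_gaussian_noise(out$image, params$noise_sigma, rng)
  out
}

#' Elastic deformation with affine jitter
#'
#' Simulates anatomical variation. A per-voxel displacement field is drawn
#' uniformly on `[-1, 1]` per axis, smoothed with a Gaussian of width
#' `sigma` voxels, and scaled by `alpha`; on top of this a random affine
#' perturbation of the identity is applied whose linear part receives
#' uniform `[-1, 1] * affine_alpha / mean(grid extent)` entries. The same
#' field warps the image (trilinear) and both masks (nearest-neighbour), so
#' the organ-inside-body relation is preserved up to boundary rounding.
#'
#' @param case A [seg_case()].
#' @param alpha Displacement scale in voxels.
#' @param sigma Field smoothing width in voxels.
#' @param affine_alpha Affine jitter scale.
#' @param rng An [rng_stream()] or `NULL`.
#' @param fill Image fill HU, `NULL` for the volume minimum.
#' @return The deformed [seg_case()].
#' @export
elastic_deform <- function(case, alpha = 38, sigma = 3.8, affine_alpha = 3.8,
                           rng = NULL, fill = NULL) {
  validate_seg_case(case)
  if (alpha < 0 || sigma < 0 || affine_alpha < 0) {
    abort_validation("alpha, sigma and affine_alpha must be >= 0.")
  }
  d <- dim(case$image$voxels)
  n <- prod(d)
  draws <- with_rng(rng, list(
    u = runif(3 * n, -1, 1),
    aff = runif(9, -1, 1)
  ))
  disp <- NULL
  if (alpha > 0) {
    disp <- numeric(3 * n)
    for (ax in 0:2) {
      f <- cpp_gauss_smooth(draws$u[(ax * n + 1):((ax + 1) * n)], d, sigma)
      disp[(ax * n + 1):((ax + 1) * n)] <- alpha * f
    }
  }
  A <- diag(3)
  if (affine_alpha > 0) {
    A <- A + matrix(draws$aff, 3, 3) * affine_alpha / mean(d)
  }
  if (is.null(disp) && affine_alpha == 0) {
    return(case)
  }
  warp_case(case, A, disp = disp, fill = fill)
}

#' Shift body density
#'
#' Draws a single HU offset from N(0, sigma^2) and adds it to every voxel
#' inside the body mask; voxels outside the body are untouched. Simulates
#' overall patient-density variation between scans.
#'
#' @param case A [seg_case()].
#' @param sigma Shift SD in HU (default 100).
#' @param rng An [rng_stream()] or `NULL`.
#' @param delta Optional fixed shift in HU, overriding the random draw.
#' @return The shifted [seg_case()].
#' @export
shift_body_density <- function(case, sigma = 100, rng = NULL, delta = NULL) {
  validate_seg_case(case)
  if (mask_count(case$body_mask) == 0) abort_validation("Body mask is empty.")
  if (sigma < 0) abort_validation("`sigma` must be >= 0.")
  if (is.null(delta)) {
    if (sigma == 0) {
      return(case)
    }
    delta <- with_rng(rng, rnorm(1, 0, sigma))
  }
  sel <- case$body_mask == 1L
  case$image$voxels[sel] <- case$image$voxels[sel] + delta
  case
}

#' Shift organ density
#'
#' As [shift_body_density()], restricted to the organ mask (default SD
#' 30 HU). Simulates gland-density variation between patients.
#'
#' @inheritParams shift_body_density
#' @param sigma Shift SD in HU (default 30).
#' @return The shifted [seg_case()].
#' @export
shift_oar_density <- function(case, sigma = 30, rng = NULL, delta = NULL) {
  validate_seg_case(case)
  if (sigma < 0) abort_validation("`sigma` must be >= 0.")
  if (is.null(delta)) {
    if (sigma == 0) {
      return(case)
    }
    delta <- with_rng(rng, rnorm(1, 0, sigma))
  }
  sel <- case$organ_mask == 1L
  case$image$voxels[sel] <- case$image$voxels[sel] + delta
  case
}

#' Domain-specific augmentation of one case
#'
#' Applies, always and in this order, elastic deformation, a body density
#' shift and an organ density shift. Operates on raw HU volumes: density
#' shifts are expressed in HU, so augmentation precedes windowing and
#' normalisation in the pipeline.
#'
#' @param case A [seg_case()].
#' @param params A [domain_aug_params()].
#' @param rng An [rng_stream()] or `NULL`.
#' @return The augmented [seg_case()].
#' @export
domain_specific_augment <- function(case, params = domain_aug_params(),
                                    rng = NULL) {
  out <- elastic_deform(
    case,
    alpha = params$elastic_alpha, sigma = params$elastic_sigma,
    affine_alpha = params$affine_alpha, rng = rng
  )
  out <- shift_body_density(out, sigma = params$body_shift_sigma, rng = rng)
  shift_oar_density(out, sigma = params$oar_shift_sigma, rng = rng)
}
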