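#' Synthetic CT phantom configuration
#'
#' Describes the phantom family the generator draws from: an elliptical body
#' of soft tissue, one low-contrast gland-like organ placed laterally inside
#' it (left or right), a bone-like posterior rod, air background, and
#' additive acquisition noise. Defaults emulate the statistical structure of
#' neck CT around the salivary glands: soft tissue around 40 HU, gland
#' around 55 HU (a 15 HU contrast, deliberately low), bone 700 HU, air
#' -1000 HU, ~1 x 1 x 2.5 mm voxels.
#'
#' Gland shape varies by random semi-axes plus a smooth direction-dependent
#' radial perturbation of relative amplitude `irregularity`, giving the
#' irregular, "oddly shaped" organs that make segmentation non-trivial.
#'
#' @param grid_shape Integer length-3 grid extent in voxels.
#' @param spacing mm per voxel, length 3.
#' @param body_hu_mean,body_hu_sd Soft-tissue HU mean and texture SD.
#' @param gland_hu_mean,gland_hu_sd Gland HU mean and texture SD.
#' @param gland_semiaxes List with components `x`, `y`, `z`, each a length-2
#'   range (voxels) the gland semi-axes are drawn from.
#' @param bone_hu,air_hu Bone rod and background HU.
#' @param noise_sd Additive global Gaussian noise SD in HU.
#' @param laterality_offset Lateral displacement of the gland centre from
#'   the midline, voxels; `NULL` for a fifth of the grid width.
#' @param irregularity Relative amplitude of the radial shape perturbation.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128, 128, 64),
                           spacing = c(1, 1, 2.5),
                           body_hu_mean = 40, body_hu_sd = 15,
                           gland_hu_mean = 55, gland_hu_sd = 10,
                           gland_semiaxes = list(
                             x = c(8, 14), y = c(8, 14), z = c(4, 7)
                           ),
                           bone_hu = 700, air_hu = -1000, noise_sd = 10,
                           laterality_offset = NULL, irregularity = 0.15) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    abort_validation("`grid_shape` must be 3 integers >= 8.")
  }
  hu <- c(body_hu_mean, gland_hu_mean, bone_hu, air_hu)
  if (any(hu < -1024) || any(hu > 3071)) {
    abort_validation("HU values must lie within [-1024, 3071].")
  }
  structure(
    list(
      grid_shape = grid_shape, spacing = as.numeric(spacing),
      body_hu_mean = body_hu_mean, body_hu_sd = body_hu_sd,
      gland_hu_mean = gland_hu_mean, gland_hu_sd = gland_hu_sd,
      gland_semiaxes = gland_semiaxes,
      bone_hu = bone_hu, air_hu = air_hu, noise_sd = noise_sd,
      laterality_offset = laterality_offset %||% round(grid_shape[1] / 5),
      irregularity = irregularity
    ),
    class = "phantom_config"
  )
}

#' Generate one synthetic CT phantom case
#'
#' Draws a [seg_case()] from the family described by a [phantom_config()]:
#' the organ and body masks are exact by construction, and generation is a
#' pure function of `(config, seed, laterality)`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @param laterality `"left"` or `"right"` — which side the gland sits on.
#' @return A valid [seg_case()].
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1,
                             laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  rng <- rng_stream(seed)
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  ix <- slice.index(array(0L, d), 1)
  iy <- slice.index(array(0L, d), 2)
  iz <- slice.index(array(0L, d), 3)

  # body: axis-aligned ellipsoid of soft tissue
  bsemi <- c(0.42 * d[1], 0.42 * d[2], 0.48 * d[3])
  body <- (((ix - ctr[1]) / bsemi[1])^2 +
    ((iy - ctr[2]) / bsemi[2])^2 +
    ((iz - ctr[3]) / bsemi[3])^2) <= 1

  draws <- with_rng(rng, list(
    semi = c(
      runif(1, config$gland_semiaxes$x[1], config$gland_semiaxes$x[2]),
      runif(1, config$gland_semiaxes$y[1], config$gland_semiaxes$y[2]),
      runif(1, config$gland_semiaxes$z[1], config$gland_semiaxes$z[2])
    ),
    jitter = c(runif(2, -2, 2), runif(1, -1, 1)),
    wave_dirs = matrix(rnorm(9), 3, 3),
    wave_freq = sample(2:4, 3, replace = TRUE),
    wave_phase = runif(3, 0, 2 * pi)
  ))
  side <- if (laterality == "left") 1 else -1
  gc <- ctr + c(side * config$laterality_offset, 0, 0) + draws$jitter

  # gland: randomised ellipsoid with a smooth radial perturbation
  ux <- (ix - gc[1]) / draws$semi[1]
  uy <- (iy - gc[2]) / draws$semi[2]
  uz <- (iz - gc[3]) / draws$semi[3]
  r <- sqrt(ux^2 + uy^2 + uz^2)
  wd <- sweep(draws$wave_dirs, 2, sqrt(colSums(draws$wave_dirs^2)), `/`)
  pert <- 0
  safe <- pmax(r, 1e-9)
  for (k in 1:3) {
    proj <- (ux * wd[1, k] + uy * wd[2, k] + uz * wd[3, k]) / safe
    pert <- pert + cos(draws$wave_freq[k] * pi * proj + draws$wave_phase[k]) / 3
  }
  gland <- r <= 1 + config$irregularity * pert
  if (any(gland & !body)) {
    abort_validation("Configuration places the gland outside the body.")
  }
  if (!any(gland)) {
    abort_validation("Configuration produced an empty gland.")
  }

  # bone rod: posterior midline cylinder along z, spine-like
  rod_r <- 0.06 * min(d[1], d[2])
  rod <- ((ix - ctr[1])^2 + (iy - (ctr[2] + 0.3 * d[2]))^2) <= rod_r^2 &
    body & !gland

  n <- prod(d)
  hu <- with_rng(rng, {
    img <- array(config$air_hu, dim = d)
    nb <- sum(body)
    img[body] <- rnorm(nb, config$body_hu_mean, config$body_hu_sd)
    ng <- sum(gland)
    img[gland] <- rnorm(ng, config$gland_hu_mean, config$gland_hu_sd)
    img[rod] <- config$bone_hu
    if (config$noise_sd > 0) {
      img <- img + array(rnorm(n, 0, config$noise_sd), dim = d)
    }
    img
  })
  hu[] <- pmin(pmax(hu, -1024), 3071)

  seg_case(
    image = ct_volume(hu, spacing = config$spacing),
    organ_mask = array(as.integer(gland), dim = d),
    body_mask = array(as.integer(body), dim = d),
    organ = "SMG", laterality = laterality,
    case_id = sprintf("phantom_s%d_%s", as.integer(seed), laterality)
  )
}

#' Generate a phantom cohort
#'
#' `n` independent phantoms with balanced lateralities (left/right counts
#' differ by at most one) and per-case seeds derived from the cohort seed.
#'
#' @param n Number of cases (>= 1).
#' @param config A [phantom_config()].
#' @param seed Cohort seed.
#' @return A named list of [seg_case()]s (names are case ids).
#' @export
generate_cohort <- function(n, config = phantom_config(), seed = 1) {
  if (n < 1) abort_validation("`n` must be >= 1.")
  lateralities <- rep(c("left", "right"), length.out = n)
  seeds <- (as.numeric(seed) + 104729 * seq_len(n)) %% 2147483647
  cases <- purrr::map2(
    seeds, lateralities,
    function(s, lat) generate_phantom(config, seed = s, laterality = lat)
  )
  stats::setNames(cases, vapply(cases, function(cs) cs$case_id, character(1)))
}

#' Expected gland volume under a phantom configuration
#'
#' First-order expectation of the gland voxel volume: `4/3 pi` times the
#' product of the mean semi-axes (the radial perturbation has zero mean and
#' contributes only at second order).
#'
#' @param config A [phantom_config()].
#' @return Expected gland volume in voxels.
#' @export
expected_gland_volume <- function(config) {
  m <- vapply(config$gland_semiaxes, mean, numeric(1))
  4 / 3 * pi * prod(m)
}
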