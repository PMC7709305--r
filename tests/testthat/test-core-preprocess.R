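test_that("NIfTI round-trip preserves voxels, masks and spacing", {
  case <- desk_case(seed = 2)
  td <- withr::local_tempdir()
  p <- file.path(td, c("img.nii.gz", "organ.nii.gz", "body.nii.gz"))
  write_case(case, p[1], p[2], p[3])
  back <- read_case(p[1], p[2], p[3], organ = "SMG", laterality = "left")
  expect_identical(back$image$voxels, case$image$voxels)
  expect_identical(back$organ_mask, case$organ_mask)
  expect_identical(back$body_mask, case$body_mask)
  expect_equal(back$image$spacing, case$image$spacing)
})

test_that("read_case rejects invalid inputs", {
  case <- desk_case(seed = 2)
  td <- withr::local_tempdir()
  p <- file.path(td, c("img.nii.gz", "organ.nii.gz", "body.nii.gz"))
  write_case(case, p[1], p[2], p[3])

  # mask with a value outside {0,1}
  bad <- case$organ_mask
  bad[1, 1, 1] <- 2L
  im <- RNifti::asNifti(bad)
  bad_path <- file.path(td, "bad.nii.gz")
  RNifti::writeNifti(im, bad_path, datatype = "uint8")
  expect_error(
    read_case(p[1], bad_path, p[3]),
    class = "oarseg_error_validation"
  )

  # organ mask not a subset of the body mask
  outside <- array(0L, dim(case$organ_mask))
  outside[1, 1, 1] <- 1L # corner voxel is air, outside the body ellipsoid
  out_path <- file.path(td, "outside.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(outside), out_path, datatype = "uint8")
  expect_error(
    read_case(p[1], out_path, p[3]),
    class = "oarseg_error_validation"
  )

  # grids that do not match
  small <- RNifti::asNifti(array(0L, c(4, 4, 2)))
  small_path <- file.path(td, "small.nii.gz")
  RNifti::writeNifti(small, small_path, datatype = "uint8")
  expect_error(
    read_case(p[1], small_path, p[3]),
    class = "oarseg_error_format"
  )
})

test_that("flip_lateral is an involution that toggles laterality", {
  case <- desk_case(seed = 5, laterality = "right")
  flipped <- flip_lateral(case)
  expect_identical(flipped$laterality, "left")
  expect_identical(sum(flipped$organ_mask), sum(case$organ_mask))
  # mirrored centroid: x -> nx + 1 - x
  nx <- dim(case$image$voxels)[1]
  cx <- mean(which(case$organ_mask == 1L, arr.ind = TRUE)[, 1])
  cx_f <- mean(which(flipped$organ_mask == 1L, arr.ind = TRUE)[, 1])
  expect_equal(cx_f, nx + 1 - cx)
  back <- flip_lateral(flipped)
  expect_identical(back$image$voxels, case$image$voxels)
  expect_identical(back$organ_mask, case$organ_mask)
  expect_identical(back$laterality, case$laterality)
})

test_that("crop_roi centres on the rounded centroid and pads out-of-bounds", {
  # organ centred at voxel 65 (0-based 64) of a 128^3 grid, SMG crop
  dims <- c(128, 128, 128)
  case <- toy_case(dims, organ_center = c(65, 65, 65), radius = 5)
  spec <- roi_spec("SMG") # 64 x 64 x 32
  cropped <- crop_roi(case, spec)
  expect_identical(dim(cropped$image$voxels), c(64L, 64L, 32L))
  # crop index ranges [33, 96] x [33, 96] x [49, 80] in 1-based coordinates
  expect_identical(
    cropped$image$voxels,
    case$image$voxels[33:96, 33:96, 49:80]
  )
  # organ fully retained
  expect_identical(sum(cropped$organ_mask), sum(case$organ_mask))

  # centroid near the x=1 face: left side must be padded with the lower bound
  case2 <- toy_case(c(64, 64, 32), organ_center = c(6, 33, 17), radius = 4)
  cropped2 <- crop_roi(case2, roi_spec("SMG", crop_shape = c(64, 64, 32)))
  expect_true(all(cropped2$image$voxels[1:20, , ] == spec$window$lower))
  expect_true(all(cropped2$organ_mask[1:20, , ] == 0L))

  # PG crop shape
  case3 <- toy_case(c(128, 128, 128), organ_center = c(65, 65, 65))
  expect_identical(
    dim(crop_roi(case3, roi_spec("PG"))$image$voxels),
    c(96L, 64L, 64L)
  )
})

test_that("crop_roi warns when the organ exceeds the crop", {
  case <- toy_case(c(64, 64, 32), radius = 10)
  spec <- roi_spec("SMG", crop_shape = c(12, 12, 8))
  expect_warning(crop_roi(case, spec), class = "oarseg_warning_crop")
})

test_that("HU windowing clips exactly and is idempotent", {
  win <- hu_window_bounds(-75, 175)
  expect_equal(win$center, 50)
  expect_equal(win$width, 250)
  v <- ct_volume(array(c(200, -100, 0, 175, -75, 42), c(6, 1, 1)))
  w <- apply_hu_window(v, win)
  expect_equal(as.numeric(w$voxels), c(175, -75, 0, 175, -75, 42))
  expect_identical(apply_hu_window(w, win)$voxels, w$voxels)
  # organ defaults
  smg <- roi_spec("SMG")$window
  pg <- roi_spec("PG")$window
  expect_equal(c(smg$lower, smg$upper), c(-75, 175))
  expect_equal(c(pg$lower, pg$upper), c(-190, 310))
})

test_that("normalisation maps window bounds to [0,1] and centres at 0", {
  win <- hu_window_bounds(-75, 175)
  v <- ct_volume(array(c(-75, 175), c(2, 1, 1)))
  n <- normalize_volume(v, win)
  expect_equal(as.numeric(n$voxels), c(-0.5, 0.5))
  const <- normalize_volume(ct_volume(array(42, c(3, 3, 3))), win)
  expect_equal(as.numeric(const$voxels), rep(0, 27))
})

test_that("preprocess_case composes crop, window, normalise", {
  case <- desk_case(seed = 9)
  pre <- preprocess_case(case, desk$roi)
  expect_identical(dim(pre$image$voxels), desk$roi$crop_shape)
  expect_lt(abs(mean(pre$image$voxels)), 1e-6)
  expect_true(all(pre$image$voxels >= -1 & pre$image$voxels <= 1))
  expect_identical(dim(pre$organ_mask), desk$roi$crop_shape)
})

test_that("centroid-centred cropping is translation-equivariant", {
  dims <- c(48, 48, 24)
  base <- toy_case(dims, organ_center = c(20, 24, 12), radius = 3)
  shifted <- toy_case(dims, organ_center = c(26, 21, 14), radius = 3)
  spec <- roi_spec("SMG", crop_shape = c(16, 16, 8))
  expect_identical(
    preprocess_case(base, spec)$image$voxels,
    preprocess_case(shifted, spec)$image$voxels
  )
})

test_that("roi_spec reads YAML configs in both window forms", {
  td <- withr::local_tempdir()
  y1 <- file.path(td, "a.yaml")
  writeLines(c(
    "organ: pg", "crop_shape: [32, 32, 16]",
    "hu_window:", "  center: 60", "  width: 500"
  ), y1)
  s1 <- roi_spec_from_yaml(y1)
  expect_identical(s1$organ, "PG")
  expect_identical(s1$crop_shape, c(32L, 32L, 16L))
  expect_equal(c(s1$window$lower, s1$window$upper), c(-190, 310))
  y2 <- file.path(td, "b.yaml")
  writeLines(c(
    "organ: smg", "hu_window:", "  lower: -75", "  upper: 175"
  ), y2)
  s2 <- roi_spec_from_yaml(y2)
  expect_equal(s2$window$center, 50)
  expect_identical(s2$crop_shape, c(64L, 64L, 32L))
})
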