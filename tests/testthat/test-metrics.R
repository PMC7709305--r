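test_that("sdc and weighted_sdc match the hand-evaluated formula", {
  p <- array(0L, c(4, 4, 2))
  r <- array(0L, c(4, 4, 2))
  p[1:4, 1, 1] <- 1L # 4 predicted
  r[1:3, 1, 1] <- 1L # 3 of them correct
  r[1:2, 2, 1] <- 1L # 2 missed
  # tp = 3, fp = 1, fn = 2
  cc <- confusion_counts(p, r)
  expect_equal(unlist(cc), c(tp = 3, fp = 1, fn = 2))
  expect_equal(sdc(p, r), 6 / 9)
  expect_equal(weighted_sdc(p, r, 0.5), 3 / 6)
  expect_equal(weighted_sdc(p, r, 0.05), 0.3 / 3.3)
  expect_equal(weighted_sdc(p, r, 1), sdc(p, r))
})

test_that("sdc edge cases and symmetry", {
  a <- array(0L, c(5, 5, 2))
  a[2:3, 2:3, 1] <- 1L
  expect_equal(sdc(a, a), 1)
  b <- array(0L, c(5, 5, 2))
  b[5, 5, 2] <- 1L
  expect_equal(sdc(a, b), 0)
  expect_equal(sdc(a, b), sdc(b, a))
  empty <- array(0L, c(5, 5, 2))
  both <- sdc(empty, empty)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  # soft map identical to its binarisation when already binary
  expect_equal(sdc(a * 1.0, a), 1)
})

test_that("weighted_sdc is monotone in w when errors exist", {
  set.seed(7)
  for (i in 1:5) {
    p <- random_mask()
    r <- random_mask()
    cc <- confusion_counts(p, r)
    if (cc$fp + cc$fn == 0) next
    ws <- vapply(c(0.05, 0.5, 1, 2), function(w) {
      as.numeric(weighted_sdc(p, r, w))
    }, numeric(1))
    expect_true(all(diff(ws) >= 0))
  }
})

test_that("hausdorff_3d matches hand values and the brute-force oracle", {
  m <- function(...) {
    a <- array(0L, c(12, 12, 12))
    for (v in list(...)) a[v[1], v[2], v[3]] <- 1L
    a
  }
  expect_equal(hausdorff_3d(m(c(1, 1, 1)), m(c(4, 5, 1))), 5)
  a <- m(c(1, 1, 1))
  b <- m(c(1, 1, 1), c(1, 1, 11))
  expect_equal(hausdorff_3d(a, b), 10)
  expect_equal(hausdorff_3d(a, a), 0)

  set.seed(42)
  for (i in 1:25) {
    x <- random_mask(c(10, 9, 8), n_fg = 30)
    y <- random_mask(c(10, 9, 8), n_fg = 30)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(hausdorff_3d(x, y), hausdorff_bruteforce(x, y))
    expect_equal(hausdorff_3d(x, y), hausdorff_3d(y, x)) # symmetry
    expect_equal(hausdorff_3d(x, x), 0) # identity
  }
  # physical spacing
  x <- m(c(1, 1, 1))
  y <- m(c(1, 1, 2))
  expect_equal(hausdorff_3d(x, y, spacing = c(1, 1, 2.5)), 2.5)
  expect_error(
    hausdorff_3d(x, array(0L, dim(x))),
    class = "oarseg_error_metric"
  )
})

test_that("contour complexity approaches 2/r on disks and scales inversely", {
  disk_mask <- function(n, r) {
    sl <- outer(seq_len(n), seq_len(n), function(i, j) {
      ((i - (n + 1) / 2)^2 + (j - (n + 1) / 2)^2) <= r^2
    })
    m <- array(0L, c(n, n, 1))
    m[, , 1] <- sl * 1L
    m
  }
  c20 <- contour_complexity(disk_mask(64, 20))
  expect_lt(abs(c20 - 2 / 20) / (2 / 20), 0.1)
  c40 <- contour_complexity(disk_mask(128, 40))
  expect_lt(abs(c40 - c20 / 2) / (c20 / 2), 0.1)
  expect_error(
    contour_complexity(array(0L, c(4, 4, 2))),
    class = "oarseg_error_metric"
  )
})

test_that("loss_spec anchors: ROI diagonal and HD normaliser", {
  x <- roi_diagonal(c(64, 64, 32))
  expect_equal(x, 96)
  spec <- loss_spec("sdc_plus_hd", roi_diagonal = x)
  expect_equal(spec$hd_normalizer, 31.68)
  expect_error(loss_spec("sdc_plus_hd"), class = "oarseg_error_validation")
})

test_that("combined loss behaves at its anchors", {
  spec <- loss_spec("sdc_plus_hd", roi_diagonal = 96)
  r <- array(0L, c(8, 8, 4))
  r[3:5, 3:5, 2:3] <- 1L
  perfect <- combined_loss(r * 1.0, r, spec)
  expect_equal(as.numeric(perfect), 0) # dice term 0, HD term 0
  # maximal HD = diagonal gives HD term 96/31.68
  expect_equal(96 / 31.68, 3.0303, tolerance = 1e-4)
  # empty prediction gets the maximal flagged HD term
  empty <- combined_loss(array(0, dim(r)), r, spec)
  expect_true(attr(empty, "empty_pred"))
  expect_equal(as.numeric(empty), 1 + 1 / 0.33)
})

test_that("dice loss gradient matches finite differences", {
  set.seed(3)
  p <- array(runif(60, 0.05, 0.95), c(5, 4, 3))
  r <- random_mask(c(5, 4, 3), n_fg = 15)
  for (w in c(1, 0.5, 0.05)) {
    lg <- oarseg:::dice_loss_grad(p, r, w = w)
    eps <- 1e-6
    for (i in c(1, 17, 42)) {
      p2 <- p
      p2[i] <- p2[i] + eps
      num <- (oarseg:::dice_loss_grad(p2, r, w = w)$value - lg$value) / eps
      expect_equal(lg$grad[i], num, tolerance = 1e-4)
    }
  }
})
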