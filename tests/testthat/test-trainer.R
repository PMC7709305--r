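test_that("model building is seed-deterministic with the shape contract", {
  m1 <- build_model(desk$model, seed = 9)
  m2 <- build_model(desk$model, seed = 9)
  m3 <- build_model(desk$model, seed = 10)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$enc1$W, m3$params$enc1$W))

  x <- array(rnorm(prod(desk$model$input_shape)), desk$model$input_shape)
  p <- oarseg:::model_forward(m1, x)$p
  expect_identical(dim(p), desk$model$input_shape)
  expect_true(all(p >= 0 & p <= 1))
  # inference is deterministic (dropout off)
  expect_identical(oarseg:::model_forward(m1, x)$p, p)

  expect_error(
    model_config(c(15, 16, 8), depth = 2),
    class = "oarseg_error_validation"
  )
})

test_that("backprop matches finite differences on a tiny model", {
  mc <- model_config(c(8, 8, 4), depth = 1, filters = 2, dropout = 0)
  model <- build_model(mc, seed = 2)
  set.seed(1)
  x <- array(rnorm(prod(mc$input_shape)), mc$input_shape)
  y <- array(0L, mc$input_shape)
  y[3:6, 3:6, 2:3] <- 1L
  spec <- loss_spec("sdc")
  loss_of <- function(m) {
    p <- oarseg:::model_forward(m, x)$p
    oarseg:::loss_value_grad(p, y, spec)$value
  }
  fw <- oarseg:::model_forward(model, x, keep_cache = TRUE)
  lg <- oarseg:::loss_value_grad(fw$p, y, spec)
  g <- oarseg:::model_backward(model, fw$cache, array(lg$grad, dim(fw$p)))
  eps <- 1e-5
  for (nm in names(model$params)) {
    for (i in seq_len(min(3, length(model$params[[nm]]$W)))) {
      m2 <- model
      m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] + eps
      num <- (loss_of(m2) - loss_of(model)) / eps
      expect_equal(g[[nm]]$dW[i], num, tolerance = 1e-3)
    }
  }
})

test_that("split_validation is disjoint, exhaustive and deterministic", {
  cases <- as.list(letters[1:20])
  sp <- split_validation(cases, 0.1, seed = 4)
  expect_equal(length(sp$val), 2)
  expect_equal(length(sp$train), 18)
  expect_setequal(c(unlist(sp$train), unlist(sp$val)), letters[1:20])
  expect_length(intersect(unlist(sp$train), unlist(sp$val)), 0)
  sp2 <- split_validation(cases, 0.1, seed = 4)
  expect_identical(sp, sp2)
  # n = 100 gives the 90/10 split
  sp3 <- split_validation(as.list(1:100), 0.1, seed = 1)
  expect_equal(length(sp3$val), 10)
  expect_error(split_validation(list(1), 0.1), class = "oarseg_error_validation")
})

test_that("the early-stopping rule follows hand-simulated traces exactly", {
  # strictly improving by >= 0.001 every epoch: never stops early
  expect_equal(early_stop_epoch(seq(0, 0.02, by = 0.002)), 11)
  # constant from epoch 1: stops after exactly 4 further epochs
  expect_equal(early_stop_epoch(rep(0.5, 20)), 5)
  # improvement resets the patience counter
  trace <- c(0.50, 0.5005, 0.5006, 0.5007, 0.52, 0.5201, 0.5202, 0.5203, 0.5204)
  # epochs 2-4 are sub-threshold (waited 3), epoch 5 improves (reset),
  # epochs 6-9 are sub-threshold again -> stop at epoch 9
  expect_equal(early_stop_epoch(trace), 9)
  # a dip below the running best counts as no improvement
  expect_equal(early_stop_epoch(c(0.6, 0.5, 0.5, 0.5, 0.5)), 5)
  # threshold is strict "< min_improvement"
  expect_equal(
    early_stop_epoch(c(0.5, 0.501, 0.502, 0.503, 0.504), 0.001, 4), 5
  )
})

test_that("train_model applies the stop rule and restores the best epoch", {
  cohort <- lapply(41:46, function(s) desk_case(seed = s))
  pre <- lapply(cohort, preprocess_case, spec = desk$roi)
  model <- build_model(desk$model, seed = 1)
  cfg <- train_config(
    loss = loss_spec("sdc"), learning_rate = 1e-2,
    max_epochs = 8, batch_size = 4, val_fraction = 0.2, seed = 3
  )
  fit <- train_model(model, pre, cfg)
  expect_s3_class(fit, "oarseg_fit")
  expect_lte(nrow(fit$log), 8)
  expect_equal(
    fit$stopped_epoch,
    early_stop_epoch(fit$log$val_metric, cfg$min_improvement, cfg$patience)
  )
  expect_equal(fit$best_epoch, which.max(fit$log$val_metric))
  # reproducibility of the whole training run
  fit2 <- train_model(build_model(desk$model, seed = 1), pre, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("prediction is deterministic with consistent binarisation", {
  case <- desk_case(seed = 51)
  model <- build_model(desk$model, seed = 6)
  p1 <- predict_case(model, case, desk$roi)
  p2 <- predict_case(model, case, desk$roi)
  expect_identical(p1$soft, p2$soft)
  expect_true(all(p1$soft >= 0 & p1$soft <= 1))
  expect_identical(p1$mask, (p1$soft >= 0.5) * 1L)
})

test_that("one-case overfitting drives training Dice above 0.9", {
  case <- desk_case(seed = 11)
  pre <- preprocess_case(case, desk$roi)
  cfg <- train_config(
    loss = loss_spec("sdc"), learning_rate = 1e-2, max_epochs = 50,
    batch_size = 1, val_fraction = 0.5, min_improvement = -Inf, seed = 2
  )
  fit <- train_model(build_model(desk$model, seed = 5), list(pre, pre), cfg)
  pred <- predict_case(fit$model, pre, desk$roi)
  expect_gt(as.numeric(sdc(pred$mask, pre$organ_mask)), 0.9)
})
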