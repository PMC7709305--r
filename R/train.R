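#' Training configuration
#'
#' Adam optimisation of the configured cost with early stopping: training
#' halts when the improvement of the monitored validation quantity over the
#' running best stays below `min_improvement` for `patience` consecutive
#' epochs (defaults 0.001 and 4). The monitored quantity is the validation
#' value of the configured cost, sign-adjusted so that higher is better; the
#' parameters of the best validation epoch are restored at the end. The
#' validation set is a random fraction (default 10%) of the training cases,
#' never used for gradient updates.
#'
#' @param loss A [loss_spec()].
#' @param learning_rate Adam learning rate.
#' @param min_improvement Early-stop improvement threshold.
#' @param patience Consecutive sub-threshold epochs before stopping.
#' @param val_fraction Validation fraction of the train set, in (0, 1).
#' @param max_epochs Epoch cap.
#' @param batch_size Cases per gradient step (gradients averaged).
#' @param seed Seed for the split, shuffling and dropout.
#' @param roi Optional [roi_spec()]; when given, raw cases passed to
#'   [train_model()] are preprocessed with it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = loss_spec("sdc"), learning_rate = 1e-3,
                         min_improvement = 0.001, patience = 4,
                         val_fraction = 0.1, max_epochs = 30, batch_size = 2,
                         seed = 1, roi = NULL) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort_validation("`val_fraction` must be in (0, 1).")
  }
  if (patience < 1) abort_validation("`patience` must be >= 1.")
  structure(
    list(
      loss = loss, learning_rate = learning_rate,
      min_improvement = min_improvement, patience = as.integer(patience),
      val_fraction = val_fraction, max_epochs = as.integer(max_epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed), roi = roi
    ),
    class = "train_config"
  )
}

#' Split cases into training and validation subsets
#'
#' Random, seed-deterministic, disjoint and exhaustive split; the validation
#' size is `round(fraction * n)`, at least 1 and at most `n - 1`.
#'
#' @param cases List of cases (or any list).
#' @param fraction Validation fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `val`.
#' @export
split_validation <- function(cases, fraction = 0.1, seed = 1) {
  n <- length(cases)
  if (n < 2) abort_validation("Need at least 2 cases to split off validation.")
  n_val <- min(n - 1L, max(1L, round(fraction * n)))
  idx <- with_rng(rng_stream(seed), sample.int(n, n_val))
  list(train = cases[-idx], val = cases[idx])
}

#' Early-stopping rule on a validation trace
#'
#' Pure form of the stop rule used by [train_model()]: walking the per-epoch
#' monitored values, the improvement at each epoch is the value minus the
#' best value seen so far; once the improvement has stayed below
#' `min_improvement` for `patience` consecutive epochs, training stops at
#' that epoch. Returns the stopping epoch, or `length(trace)` if the rule
#' never fires.
#'
#' @param trace Numeric vector of per-epoch monitored values (higher =
#'   better).
#' @param min_improvement Improvement threshold (default 0.001).
#' @param patience Consecutive sub-threshold epochs required (default 4).
#' @return Integer epoch index at which training stops.
#' @examples
#' early_stop_epoch(c(0.5, rep(0.5, 10))) # stops at epoch 5
#' @export
early_stop_epoch <- function(trace, min_improvement = 0.001, patience = 4) {
  best <- -Inf
  waited <- 0L
  for (t in seq_along(trace)) {
    improvement <- trace[t] - best
    best <- max(best, trace[t])
    if (improvement < min_improvement) {
      waited <- waited + 1L
      if (waited >= patience) {
        return(t)
      }
    } else {
      waited <- 0L
    }
  }
  length(trace)
}

adam_init <- function(params) {
  lapply(params, function(p) {
    list(
      mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
      mb = numeric(length(p$b)), vb = numeric(length(p$b))
    )
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mW_hat <- s$mW / (1 - beta1^t)
    vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

case_xy <- function(case, roi) {
  pre <- if (!is.null(attr(case, "preprocessed"))) {
    case
  } else {
    if (is.null(roi)) {
      abort_validation(
        "Cases are not preprocessed and the train config has no `roi`."
      )
    }
    preprocess_case(case, roi)
  }
  list(x = pre$image$voxels, y = pre$organ_mask)
}

#' Train a segmentation model
#'
#' Mini-batch Adam on the configured cost with the early-stopping rule of
#' [early_stop_epoch()]. The validation subset is split off the training
#' cases first and never used for gradient updates; the parameters of the
#' best validation epoch are restored before returning. Aborts with a
#' diagnostic if the loss turns non-finite.
#'
#' @param model An `oarseg_model` from [build_model()].
#' @param cases List of [seg_case()]s (preprocessed, or raw with
#'   `cfg$roi` set).
#' @param cfg A [train_config()].
#' @return An object of class `oarseg_fit`: list with `model` (best
#'   parameters), `log` (per-epoch tibble), `stopped_epoch`, `best_epoch`
#'   and `config`.
#' @export
train_model <- function(model, cases, cfg = train_config()) {
  if (length(cases) < 2) abort_validation("Need at least 2 cases to train.")
  data <- lapply(cases, case_xy, roi = cfg$roi)
  split <- split_validation(data, cfg$val_fraction, seed = cfg$seed)
  tr <- split$train
  va <- split$val
  rng <- rng_stream(cfg$seed + 1L)
  state <- adam_init(model$params)
  spec <- cfg$loss

  val_loss_of <- function(m) {
    mean(vapply(va, function(d) {
      pr <- model_forward(m, d$x)$p
      loss_value_grad(pr, d$y, spec)$value
    }, numeric(1)))
  }

  log_rows <- list()
  best_metric <- -Inf
  best_params <- model$params
  best_epoch <- 0L
  waited <- 0L
  step_t <- 0L
  stopped <- cfg$max_epochs

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_rng(rng, sample.int(length(tr)))
    train_losses <- numeric(0)
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in bidx) {
        d <- tr[[i]]
        fw <- model_forward(model, d$x, train = TRUE, rng = rng,
                            keep_cache = TRUE)
        lg <- loss_value_grad(fw$p, d$y, spec)
        if (!is.finite(lg$value)) {
          abort(
            sprintf("Non-finite loss at epoch %d.", epoch),
            class = c("oarseg_error_numeric", "oarseg_error")
          )
        }
        train_losses <- c(train_losses, lg$value)
        g <- model_backward(model, fw$cache, array(lg$grad, dim(fw$p)))
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in names(acc)) {
            acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
            acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
          }
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$dW <- acc[[nm]]$dW / length(bidx)
        acc[[nm]]$db <- acc[[nm]]$db / length(bidx)
      }
      step_t <- step_t + 1L
      upd <- adam_step(model$params, acc, state, cfg$learning_rate, step_t)
      model$params <- upd$params
      state <- upd$state
    }
    val_loss <- val_loss_of(model)
    metric <- -val_loss # sign-adjusted: higher is better
    improvement <- metric - best_metric
    if (metric > best_metric) {
      best_params <- model$params
      best_epoch <- epoch
    }
    best_metric <- max(best_metric, metric)
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(train_losses), val_loss = val_loss,
      val_metric = metric, improvement = improvement
    )
    if (improvement < cfg$min_improvement) {
      waited <- waited + 1L
      if (waited >= cfg$patience) {
        stopped <- epoch
        break
      }
    } else {
      waited <- 0L
    }
  }
  model$params <- best_params
  structure(
    list(
      model = model, log = dplyr::bind_rows(log_rows),
      stopped_epoch = stopped, best_epoch = best_epoch, config = cfg
    ),
    class = "oarseg_fit"
  )
}

#' @export
print.oarseg_fit <- function(x, ...) {
  cat(sprintf(
    "<oarseg_fit> %d epochs (best at %d), final val loss %.4f\n",
    nrow(x$log), x$best_epoch, x$log$val_loss[nrow(x$log)]
  ))
  invisible(x)
}

#' @export
tidy.oarseg_fit <- function(x, ...) x$log

#' @export
glance.oarseg_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_metric = max(x$log$val_metric),
    final_train_loss = x$log$train_loss[nrow(x$log)]
  )
}
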