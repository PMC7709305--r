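#' Model configuration for the 3D fully-convolutional segmenter
#'
#' A compact 3D U-net-style encoder-decoder: `depth` encoder levels of
#' (3x3x3 convolution, ReLU, dropout, 2x max-pool), a bottleneck
#' convolution, and a mirrored decoder with nearest-neighbour upsampling and
#' skip connections, closed by a 1x1x1 convolution and voxel-wise sigmoid.
#' Dropout is applied after every convolutional layer (training only).
#' The input shape must be divisible by `2^depth` along every axis.
#'
#' Defaults are desk-scale (depth 2, 8 base filters); the architecture is a
#' configuration, not a constant, so scaling up is a parameter change.
#'
#' @param input_shape Integer length-3 crop shape the model operates on.
#' @param depth Number of encoder levels.
#' @param filters Filters at the first level; doubled per level.
#' @param dropout Dropout rate on all convolutional layers, in `[0, 1)`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape, depth = 2, filters = 8, dropout = 0.2) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape < 1)) {
    abort_validation("`input_shape` must be 3 positive integers.")
  }
  if (any(input_shape %% (2^depth) != 0)) {
    abort_validation(sprintf(
      "Input shape (%s) must be divisible by 2^depth = %d along every axis.",
      paste(input_shape, collapse = "x"), 2^depth
    ))
  }
  if (dropout < 0 || dropout >= 1) abort_validation("`dropout` must be in [0, 1).")
  structure(
    list(
      input_shape = input_shape, depth = as.integer(depth),
      filters = as.integer(filters), dropout = dropout
    ),
    class = "model_config"
  )
}

layer_channels <- function(config) {
  f <- config$filters
  D <- config$depth
  layers <- list()
  for (d in seq_len(D)) {
    layers[[paste0("enc", d)]] <- c(
      cin = if (d == 1) 1L else as.integer(f * 2^(d - 2)),
      cout = as.integer(f * 2^(d - 1)), k = 3L
    )
  }
  layers$bott <- c(
    cin = as.integer(f * 2^(D - 1)), cout = as.integer(f * 2^D), k = 3L
  )
  for (d in rev(seq_len(D))) {
    layers[[paste0("dec", d)]] <- c(
      cin = as.integer(f * 2^d + f * 2^(d - 1)),
      cout = as.integer(f * 2^(d - 1)), k = 3L
    )
  }
  layers$out <- c(cin = f, cout = 1L, k = 1L)
  layers
}

#' Build a segmentation model with seeded initialisation
#'
#' He-normal weight initialisation, deterministic given `seed`: two builds
#' with the same seed have identical parameters, two different seeds differ
#' — the prerequisite for initialisation-diversity ensembles.
#'
#' @param config A [model_config()].
#' @param seed Integer initialisation seed.
#' @return An object of class `oarseg_model`.
#' @export
build_model <- function(config, seed = 1) {
  rng <- rng_stream(seed)
  chans <- layer_channels(config)
  params <- with_rng(rng, lapply(chans, function(ch) {
    fan_in <- ch[["k"]]^3 * ch[["cin"]]
    list(
      W = matrix(
        rnorm(ch[["cout"]] * fan_in, sd = sqrt(2 / fan_in)),
        nrow = ch[["cout"]]
      ),
      b = numeric(ch[["cout"]]),
      k = ch[["k"]], cin = ch[["cin"]], cout = ch[["cout"]]
    )
  }))
  structure(
    list(config = config, params = params, seed = as.integer(seed)),
    class = "oarseg_model"
  )
}

#' @export
print.oarseg_model <- function(x, ...) {
  npar <- sum(vapply(
    x$params, function(p) length(p$W) + length(p$b), numeric(1)
  ))
  cat(sprintf(
    "<oarseg_model> input %s, depth %d, %d base filters, dropout %.2f, %d parameters\n",
    paste(x$config$input_shape, collapse = "x"), x$config$depth,
    x$config$filters, x$config$dropout, npar
  ))
  invisible(x)
}

conv_fwd <- function(layer, x4) {
  dims <- dim(x4)
  cols <- cpp_im2col3(x4, as.integer(dims), layer$k)
  y <- layer$W %*% cols + layer$b
  list(
    y = array(t(y), c(dims[1:3], layer$cout)),
    cols = cols, in_dims = as.integer(dims)
  )
}

conv_bwd <- function(layer, cache, dy) {
  n <- prod(cache$in_dims[1:3])
  dym <- t(matrix(dy, n, layer$cout))
  dcols <- crossprod(layer$W, dym)
  list(
    dW = dym %*% t(cache$cols),
    db = rowSums(dym),
    dx = array(cpp_col2im3(dcols, cache$in_dims, layer$k), cache$in_dims)
  )
}

dropout_fwd <- function(x, rate, train, rng) {
  if (!train || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- array(
    (with_rng(rng, runif(length(x))) >= rate) / (1 - rate),
    dim = dim(x)
  )
  list(y = x * mask, mask = mask)
}

# Full forward pass; returns the sigmoid probability map and, when
# `keep_cache`, everything the backward pass needs.
model_forward <- function(model, x, train = FALSE, rng = NULL,
                          keep_cache = FALSE) {
  cfg <- model$config
  if (!identical(dim(x), cfg$input_shape)) {
    abort_format(sprintf(
      "Input shape (%s) does not match model input (%s).",
      paste(dim(x), collapse = "x"), paste(cfg$input_shape, collapse = "x")
    ))
  }
  D <- cfg$depth
  p <- model$params
  cur <- array(as.numeric(x), c(dim(x), 1L))
  cache <- list(stages = list())
  skips <- list()
  for (d in seq_len(D)) {
    nm <- paste0("enc", d)
    cv <- conv_fwd(p[[nm]], cur)
    rl <- pmax(cv$y, 0)
    dp <- dropout_fwd(rl, cfg$dropout, train, rng)
    skips[[d]] <- dp$y
    pl <- cpp_maxpool3_fwd(dp$y, as.integer(dim(dp$y)))
    cur <- array(pl$y, c(dim(dp$y)[1:3] %/% 2L, dim(dp$y)[4]))
    if (keep_cache) {
      cache$stages[[nm]] <- list(
        conv = cv, pre_relu = cv$y, drop_mask = dp$mask,
        pool_idx = pl$idx, pool_in_dims = as.integer(dim(dp$y))
      )
    }
  }
  cv <- conv_fwd(p$bott, cur)
  rl <- pmax(cv$y, 0)
  dp <- dropout_fwd(rl, cfg$dropout, train, rng)
  cur <- dp$y
  if (keep_cache) {
    cache$stages$bott <- list(
      conv = cv, pre_relu = cv$y, drop_mask = dp$mask
    )
  }
  for (d in rev(seq_len(D))) {
    nm <- paste0("dec", d)
    up <- array(
      cpp_upsample2_fwd(cur, as.integer(dim(cur))),
      c(2L * dim(cur)[1:3], dim(cur)[4])
    )
    skip <- skips[[d]]
    cat_in <- array(c(up, skip), c(dim(up)[1:3], dim(up)[4] + dim(skip)[4]))
    cv <- conv_fwd(p[[nm]], cat_in)
    rl <- pmax(cv$y, 0)
    dp <- dropout_fwd(rl, cfg$dropout, train, rng)
    cur <- dp$y
    if (keep_cache) {
      cache$stages[[nm]] <- list(
        conv = cv, pre_relu = cv$y, drop_mask = dp$mask,
        up_in_dims = as.integer(c(dim(cat_in)[1:3] %/% 2L, dim(up)[4])),
        n_up_channels = dim(up)[4]
      )
    }
  }
  cv <- conv_fwd(p$out, cur)
  z <- cv$y
  prob <- 1 / (1 + exp(-z))
  out_p <- array(prob, dim(x))
  if (keep_cache) {
    cache$stages$out <- list(conv = cv)
    cache$prob <- prob
    list(p = out_p, cache = cache)
  } else {
    list(p = out_p)
  }
}

# Backward pass from dL/dprob; returns gradients in the same layout as
# model$params.
model_backward <- function(model, cache, dldp) {
  cfg <- model$config
  D <- cfg$depth
  p <- model$params
  grads <- list()
  prob <- cache$prob
  dz <- array(as.numeric(dldp) * as.numeric(prob) * (1 - as.numeric(prob)),
    dim = dim(prob)
  )
  bw <- conv_bwd(p$out, cache$stages$out$conv, dz)
  grads$out <- list(dW = bw$dW, db = bw$db)
  dcur <- bw$dx
  for (d in seq_len(D)) { # decoder levels, shallow to deep
    nm <- paste0("dec", d)
    st <- cache$stages[[nm]]
    if (!is.null(st$drop_mask)) dcur <- dcur * st$drop_mask
    dcur <- dcur * (st$pre_relu > 0)
    bw <- conv_bwd(p[[nm]], st$conv, dcur)
    grads[[nm]] <- list(dW = bw$dW, db = bw$db)
    nup <- st$n_up_channels
    dims <- dim(bw$dx)
    dup <- bw$dx[, , , seq_len(nup), drop = FALSE]
    dskip <- bw$dx[, , , nup + seq_len(dims[4] - nup), drop = FALSE]
    grads[[paste0(".skip", d)]] <- dskip
    dcur <- array(
      cpp_upsample2_bwd(dup, st$up_in_dims),
      st$up_in_dims
    )
  }
  st <- cache$stages$bott
  if (!is.null(st$drop_mask)) dcur <- dcur * st$drop_mask
  dcur <- dcur * (st$pre_relu > 0)
  bw <- conv_bwd(p$bott, st$conv, dcur)
  grads$bott <- list(dW = bw$dW, db = bw$db)
  dcur <- bw$dx
  for (d in rev(seq_len(D))) { # encoder levels, deep to shallow
    nm <- paste0("enc", d)
    st <- cache$stages[[nm]]
    dpooled <- array(
      cpp_maxpool3_bwd(dcur, st$pool_idx, st$pool_in_dims),
      st$pool_in_dims
    )
    dpooled <- dpooled + grads[[paste0(".skip", d)]]
    grads[[paste0(".skip", d)]] <- NULL
    if (!is.null(st$drop_mask)) dpooled <- dpooled * st$drop_mask
    dpooled <- dpooled * (st$pre_relu > 0)
    bw <- conv_bwd(p[[nm]], st$conv, dpooled)
    grads[[nm]] <- list(dW = bw$dW, db = bw$db)
    dcur <- bw$dx
  }
  grads[names(model$params)]
}

#' Run inference on a case
#'
#' Preprocesses the case (unless it already carries the `"preprocessed"`
#' attribute), runs a deterministic forward pass (dropout disabled) and
#' thresholds the probability map at 0.5.
#'
#' @param model A trained or freshly built `oarseg_model`, or an
#'   `oarseg_fit` from [train_model()].
#' @param case A [seg_case()].
#' @param spec The [roi_spec()] to preprocess with.
#' @return A list with `soft` (probability array), `mask` (binary array) and
#'   `case` (the preprocessed [seg_case()] carrying the reference masks on
#'   the crop grid).
#' @export
predict_case <- function(model, case, spec) {
  if (inherits(model, "oarseg_fit")) model <- model$model
  pre <- if (!is.null(attr(case, "preprocessed"))) {
    case
  } else {
    preprocess_case(case, spec)
  }
  soft <- model_forward(model, pre$image$voxels)$p
  mask <- (soft >= 0.5) * 1L
  dim(mask) <- dim(soft)
  list(soft = soft, mask = mask, case = pre)
}
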