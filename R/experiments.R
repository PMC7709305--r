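#' Six-fold cross-validation plan
#'
#' Random balanced partition of the case ids into `k` disjoint test folds
#' whose union is the full cohort; each fold's train set is the complement
#' of its test set. Deterministic given the seed.
#'
#' @param case_ids Character vector of case ids.
#' @param seed Integer seed.
#' @param k Number of folds (default 6).
#' @return An object of class `fold_plan`: list with `k`, `seed` and
#'   `folds`, each fold a list with `test_ids` and `train_ids`.
#' @export
make_folds <- function(case_ids, seed = 1, k = 6) {
  n <- length(case_ids)
  if (n < k) {
    abort_validation(sprintf("Need at least %d cases for %d folds.", k, k))
  }
  perm <- case_ids[with_rng(rng_stream(seed), sample.int(n))]
  assignment <- rep(seq_len(k), length.out = n)
  folds <- lapply(seq_len(k), function(f) {
    test <- perm[assignment == f]
    list(test_ids = test, train_ids = setdiff(case_ids, test))
  })
  structure(list(k = k, seed = as.integer(seed), folds = folds),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test_ids), integer(1))
  cat(sprintf(
    "<fold_plan> %d folds over %d cases (test sizes %s)\n",
    x$k, sum(sizes), paste(sizes, collapse = "/")
  ))
  invisible(x)
}

fold_seed <- function(seed, fold, offset = 0) {
  as.integer((as.numeric(seed) * 1009 + fold * 131 + offset * 7) %% 2147483629)
}

new_experiment_result <- function(per_case, design, meta = list()) {
  structure(
    list(per_case = per_case, design = design, meta = meta),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> design=%s, %d case rows\n", x$design,
    nrow(x$per_case)
  ))
  print(aggregate(x))
  invisible(x)
}

#' @export
tidy.experiment_result <- function(x, ...) x$per_case

#' Aggregate an experiment result to mean and SD
#'
#' Combined over all cross-validation folds (not an average of per-fold
#' means), with the sample SD (`n - 1` denominator). Labels are formatted to
#' two decimals for the Dice coefficient and one for the Hausdorff distance.
#' A single-row result reports SD 0, flagged by `n = 1`.
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `mean`, `sd`, `n`, `label`.
#' @export
aggregate.experiment_result <- function(x, ...) {
  agg_one <- function(v, digits) {
    v <- v[is.finite(v)]
    n <- length(v)
    m <- mean(v)
    s <- if (n <= 1) 0 else stats::sd(v)
    fmt <- paste0("%.", digits, "f ± %.", digits, "f")
    tibble::tibble(mean = m, sd = s, n = n, label = sprintf(fmt, m, s))
  }
  dplyr::bind_rows(
    dplyr::mutate(agg_one(x$per_case$sdc, 2), metric = "sdc", .before = 1),
    dplyr::mutate(agg_one(x$per_case$hd, 1), metric = "hd", .before = 1)
  )
}

# Shared fold runner: trains one model per fold and evaluates its test
# cases. `augment_fn(case, rng)` generates one augmented copy of a raw
# case; `n_aug` copies are drawn from the fold's train cases only (sampling
# with replacement), so no test case ever influences its own fold's
# training.
run_folds <- function(cohort, plan, base_cfg, seed, augment_fn = NULL,
                      n_aug = 0) {
  rows <- list()
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    train_raw <- cohort[fold$train_ids]
    if (n_aug > 0 && !is.null(augment_fn)) {
      rng <- rng_stream(fold_seed(seed, f, offset = 1))
      src <- with_rng(rng, sample(length(train_raw), n_aug, replace = TRUE))
      aug <- lapply(src, function(i) augment_fn(train_raw[[i]], rng))
      train_raw <- c(train_raw, aug)
    }
    train_pre <- lapply(train_raw, preprocess_case, spec = base_cfg$roi)
    cfg <- base_cfg$train
    cfg$seed <- fold_seed(seed, f)
    model <- build_model(base_cfg$model, seed = fold_seed(seed, f, offset = 2))
    fit <- train_model(model, train_pre, cfg)
    for (id in fold$test_ids) {
      pred <- predict_case(fit$model, cohort[[id]], base_cfg$roi)
      ref <- pred$case$organ_mask
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = f, case_id = id,
        sdc = as.numeric(sdc(pred$mask, ref)),
        hd = if (sum(pred$mask) == 0) NA_real_ else hausdorff_3d(pred$mask, ref)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Set-size experiment
#'
#' Trains the base model on nested subsamples of the cohort at each
#' requested size, with six-fold cross-validation inside each size, and
#' tabulates per-case test metrics per size. Reproduces the
#' set-size-versus-performance design at whatever sizes the cohort allows.
#'
#' @param cohort Named list of raw [seg_case()]s.
#' @param sizes Integer vector of training-cohort sizes.
#' @param base_cfg List with `roi` ([roi_spec()]), `model` ([model_config()])
#'   and `train` ([train_config()]).
#' @param seed Experiment seed.
#' @return List of class `size_sweep`: per-size `experiment_result`s plus a
#'   combined `summary` tibble.
#' @export
run_set_size_experiment <- function(cohort, sizes, base_cfg, seed = 1) {
  if (max(sizes) > length(cohort)) {
    abort_validation("Requested size exceeds the cohort.")
  }
  ids <- names(cohort)
  perm <- ids[with_rng(rng_stream(seed), sample.int(length(ids)))]
  results <- lapply(sizes, function(sz) {
    sub <- perm[seq_len(sz)] # nested subsamples: smaller sets are contained
    plan <- make_folds(sub, seed = fold_seed(seed, 0, sz))
    per_case <- run_folds(cohort[sub], plan, base_cfg, seed)
    new_experiment_result(per_case, "set_size", meta = list(size = sz))
  })
  names(results) <- as.character(sizes)
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(aggregate(r), size = r$meta$size, .before = 1)
  }))
  structure(list(results = results, summary = summary), class = "size_sweep")
}

#' Data-augmentation experiment
#'
#' For each requested count, adds that many augmented copies (traditional or
#' domain-specific) of randomly drawn fold-train cases (with replacement) to
#' each fold's training set; test sets are untouched and augmented copies
#' inherit their source's fold, so there is no train/test leakage.
#'
#' @inheritParams run_set_size_experiment
#' @param mode `"traditional"` or `"domain"`.
#' @param counts Integer vector of augmented-copy counts (0 = base).
#' @return List of class `aug_sweep` analogous to [run_set_size_experiment()].
#' @export
run_augmentation_experiment <- function(cohort, mode = c("traditional", "domain"),
                                        counts, base_cfg, seed = 1) {
  mode <- match.arg(mode)
  organ <- base_cfg$roi$organ
  augment_fn <- if (mode == "traditional") {
    params <- traditional_aug_params()
    function(case, rng) traditional_augment(case, params, rng)
  } else {
    params <- domain_aug_params(organ)
    function(case, rng) domain_specific_augment(case, params, rng)
  }
  plan <- make_folds(names(cohort), seed = seed)
  results <- lapply(counts, function(ct) {
    per_case <- run_folds(
      cohort, plan, base_cfg, seed,
      augment_fn = if (ct > 0) augment_fn else NULL, n_aug = ct
    )
    new_experiment_result(
      per_case, paste0("augment_", mode),
      meta = list(count = ct, mode = mode)
    )
  })
  names(results) <- as.character(counts)
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(aggregate(r), count = r$meta$count, .before = 1)
  }))
  structure(list(results = results, summary = summary), class = "aug_sweep")
}

#' Cost-function experiment
#'
#' Trains the base set-up once per cost specification with identical folds
#' and identical initialisation seeds, so the cost is the only varying
#' factor.
#'
#' @inheritParams run_set_size_experiment
#' @param loss_specs Named list of [loss_spec()]s, e.g. plain Dice,
#'   weighted Dice at 0.5 and 0.05, and Dice+Hausdorff.
#' @return List of class `cost_sweep` with one `experiment_result` per cost.
#' @export
run_cost_function_experiment <- function(cohort, loss_specs, base_cfg,
                                         seed = 1) {
  if (!all(vapply(loss_specs, inherits, logical(1), "loss_spec"))) {
    abort_validation("All entries of `loss_specs` must be loss_spec objects.")
  }
  plan <- make_folds(names(cohort), seed = seed)
  results <- lapply(loss_specs, function(spec) {
    cfg <- base_cfg
    cfg$train$loss <- spec
    per_case <- run_folds(cohort, plan, cfg, seed)
    new_experiment_result(per_case, "cost_function", meta = list(loss = spec))
  })
  summary <- dplyr::bind_rows(lapply(names(results), function(nm) {
    dplyr::mutate(aggregate(results[[nm]]), loss = nm, .before = 1)
  }))
  structure(
    list(results = results, summary = summary, plan = plan),
    class = "cost_sweep"
  )
}

#' Ensemble experiment
#'
#' Per fold, trains `n_models` models differing only in their random
#' initialisation (and training stochasticity), evaluates every cut-off of
#' the voxel-vote ensemble on each test case, and reports the stand-alone
#' baseline (mean and SD over the individual members) alongside.
#'
#' @inheritParams run_set_size_experiment
#' @param n_models Ensemble size (default 11).
#' @return List of class `ensemble_experiment` with `per_case` (tibble
#'   `fold`, `case_id`, `cutoff`, `sdc`, `hd`), `cutoff_summary`,
#'   `standalone` and `standalone_summary`.
#' @export
run_ensemble_experiment <- function(cohort, n_models = 11, base_cfg, seed = 1) {
  if (n_models < 2) abort_validation("`n_models` must be >= 2.")
  plan <- make_folds(names(cohort), seed = seed)
  rows <- list()
  solo <- list()
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    train_pre <- lapply(
      cohort[fold$train_ids], preprocess_case,
      spec = base_cfg$roi
    )
    fits <- lapply(seq_len(n_models), function(m) {
      cfg <- base_cfg$train
      cfg$seed <- fold_seed(seed, f, offset = 10 + m)
      model <- build_model(
        base_cfg$model,
        seed = fold_seed(seed, f, offset = 100 + m)
      )
      train_model(model, train_pre, cfg)
    })
    for (id in fold$test_ids) {
      pre <- preprocess_case(cohort[[id]], base_cfg$roi)
      preds <- lapply(fits, function(fit) {
        predict_case(fit$model, pre, base_cfg$roi)$mask
      })
      sw <- sweep_cutoffs(preds, pre$organ_mask)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        sw$table,
        fold = f, case_id = id, .before = 1
      )
      solo[[length(solo) + 1L]] <- dplyr::mutate(
        sw$standalone,
        fold = f, case_id = id, .before = 1
      )
    }
  }
  per_case <- dplyr::bind_rows(rows)
  standalone <- dplyr::bind_rows(solo)
  cutoff_summary <- dplyr::summarise(
    dplyr::group_by(per_case, .data$cutoff),
    sdc_mean = mean(.data$sdc), sdc_sd = stats::sd(.data$sdc),
    hd_mean = mean(.data$hd, na.rm = TRUE),
    hd_sd = stats::sd(.data$hd, na.rm = TRUE),
    .groups = "drop"
  )
  structure(
    list(
      per_case = per_case, cutoff_summary = cutoff_summary,
      standalone = standalone,
      standalone_summary = tibble::tibble(
        metric = c("sdc", "hd"),
        mean = c(
          mean(standalone$sdc), mean(standalone$hd, na.rm = TRUE)
        ),
        sd = c(
          stats::sd(standalone$sdc), stats::sd(standalone$hd, na.rm = TRUE)
        )
      ),
      n_models = n_models, plan = plan
    ),
    class = "ensemble_experiment"
  )
}

#' Combined-strategy experiment
#'
#' Pairs, on identical folds and test cases, (arm A) a single model trained
#' on the full training set against (arm B) an ensemble of models trained on
#' the training set doubled by domain-specific augmentation, evaluated with
#' patient-specific HU windowing (the ensemble majority vote is the
#' predictor the window search scores).
#'
#' @inheritParams run_set_size_experiment
#' @param n_models Ensemble size for arm B.
#' @param grid [window_grid()] searched per test case in arm B.
#' @return List of class `combined_experiment` with `per_case` (paired
#'   tibble) and `summary`.
#' @export
run_combined_experiment <- function(cohort, base_cfg, seed = 1, n_models = 5,
                                    grid = window_grid()) {
  plan <- make_folds(names(cohort), seed = seed)
  organ <- base_cfg$roi$organ
  aug_params <- domain_aug_params(organ)
  rows <- list()
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    train_raw <- cohort[fold$train_ids]
    train_pre <- lapply(train_raw, preprocess_case, spec = base_cfg$roi)

    # arm A: single model, base training set
    cfg_a <- base_cfg$train
    cfg_a$seed <- fold_seed(seed, f)
    fit_a <- train_model(
      build_model(base_cfg$model, seed = fold_seed(seed, f, offset = 2)),
      train_pre, cfg_a
    )

    # arm B: train set doubled by domain-specific augmentation + ensemble
    rng <- rng_stream(fold_seed(seed, f, offset = 1))
    src <- with_rng(
      rng,
      sample(length(train_raw), length(train_raw), replace = TRUE)
    )
    aug <- lapply(src, function(i) {
      domain_specific_augment(train_raw[[i]], aug_params, rng)
    })
    train_b <- c(train_pre, lapply(aug, preprocess_case, spec = base_cfg$roi))
    fits_b <- lapply(seq_len(n_models), function(m) {
      cfg <- base_cfg$train
      cfg$seed <- fold_seed(seed, f, offset = 10 + m)
      train_model(
        build_model(
          base_cfg$model,
          seed = fold_seed(seed, f, offset = 100 + m)
        ),
        train_b, cfg
      )
    })
    cut <- majority_cutoff(n_models)
    ens_predict <- function(pre_case) {
      preds <- lapply(fits_b, function(fit) {
        predict_case(fit$model, pre_case, base_cfg$roi)$mask
      })
      out <- (unclass(vote(preds)) >= cut) * 1
      dim(out) <- dim(preds[[1]])
      out
    }

    for (id in fold$test_ids) {
      pred_a <- predict_case(fit_a$model, cohort[[id]], base_cfg$roi)
      ref_a <- pred_a$case$organ_mask
      search <- search_best_window(
        ens_predict, cohort[[id]], base_cfg$roi, grid
      )
      spec_b <- roi_spec(
        organ,
        crop_shape = base_cfg$roi$crop_shape, window = search$best_window
      )
      pre_b <- preprocess_case(cohort[[id]], spec_b)
      mask_b <- ens_predict(pre_b)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = f, case_id = id,
        sdc_a = as.numeric(sdc(pred_a$mask, ref_a)),
        hd_a = if (sum(pred_a$mask) == 0) {
          NA_real_
        } else {
          hausdorff_3d(pred_a$mask, ref_a)
        },
        sdc_b = search$best_sdc,
        hd_b = if (sum(mask_b) == 0) {
          NA_real_
        } else {
          hausdorff_3d(mask_b, pre_b$organ_mask)
        }
      )
    }
  }
  per_case <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    arm = c("single_max_size", "combined"),
    sdc_mean = c(mean(per_case$sdc_a), mean(per_case$sdc_b)),
    sdc_sd = c(stats::sd(per_case$sdc_a), stats::sd(per_case$sdc_b)),
    hd_mean = c(
      mean(per_case$hd_a, na.rm = TRUE), mean(per_case$hd_b, na.rm = TRUE)
    ),
    hd_sd = c(
      stats::sd(per_case$hd_a, na.rm = TRUE),
      stats::sd(per_case$hd_b, na.rm = TRUE)
    )
  )
  structure(
    list(per_case = per_case, summary = summary, plan = plan),
    class = "combined_experiment"
  )
}

#' Desk-scale study configuration
#'
#' The fixed desk-scale conditions used throughout the package's own
#' simulations, chosen once for single-CPU feasibility: a 48 x 48 x 24
#' phantom grid at 1 x 1 x 2.5 mm, gland semi-axes 4-6 / 4-6 / 2-3 voxels, a
#' 16 x 16 x 8 region-of-interest with the organ's default window, a
#' depth-2 / 4-filter model with dropout 0.2, and Adam at learning rate
#' 0.01 with batch size 4. See the package vignette for the rationale.
#'
#' @param organ `"SMG"` or `"PG"` (sets window and augmentation defaults).
#' @param max_epochs Epoch cap for the desk-scale runs.
#' @return List with components `phantom` ([phantom_config()]), `roi`
#'   ([roi_spec()]), `model` ([model_config()]), `train` ([train_config()]),
#'   `n_models` and `grid` (a coarse [window_grid()]).
#' @export
desk_scale_config <- function(organ = "SMG", max_epochs = 12) {
  roi <- roi_spec(organ, crop_shape = c(16, 16, 8))
  list(
    phantom = phantom_config(
      grid_shape = c(48, 48, 24), spacing = c(1, 1, 2.5),
      gland_semiaxes = list(x = c(4, 6), y = c(4, 6), z = c(2, 3)),
      laterality_offset = 10, irregularity = 0.12
    ),
    roi = roi,
    model = model_config(input_shape = c(16, 16, 8), depth = 2, filters = 4),
    train = train_config(
      loss = loss_spec("sdc"), learning_rate = 1e-2,
      max_epochs = max_epochs, batch_size = 4
    ),
    n_models = 5,
    grid = window_grid(
      centers = seq(-100, 400, by = 100),
      widths = seq(100, 1000, by = 300)
    )
  )
}
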