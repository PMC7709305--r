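#' Patient-specific window search grid
#'
#' The standard grid of candidate HU windows: centres from -100 to 400 HU in
#' steps of 10 (51 values) crossed with widths from 100 to 1000 HU in steps
#' of 50 (19 values) — 969 windows in centre-major, width-minor scan order.
#' Both range endpoints are inclusive.
#'
#' @param centers,widths Numeric vectors of candidate centres and widths
#'   (HU); defaults give the standard grid.
#' @return A tibble of class `window_grid` with columns `center`, `width`.
#' @examples
#' nrow(window_grid()) # 969
#' @export
window_grid <- function(centers = seq(-100, 400, by = 10),
                        widths = seq(100, 1000, by = 50)) {
  if (any(widths <= 0)) abort_validation("All widths must be > 0.")
  grid <- tibble::tibble(
    center = rep(centers, each = length(widths)),
    width = rep(widths, times = length(centers))
  )
  class(grid) <- c("window_grid", class(grid))
  grid
}

as_predictor <- function(predictor) {
  if (inherits(predictor, "oarseg_model")) {
    model <- predictor
    function(pre_case) model_forward(model, pre_case$image$voxels)$p
  } else if (is.function(predictor)) {
    predictor
  } else {
    abort_validation("`predictor` must be a function or an oarseg_model.")
  }
}

#' Search the best patient-specific HU window
#'
#' For every candidate window the case is re-preprocessed (crop, clip to
#' that window, normalise), the predictor is run, its soft output binarised
#' at 0.5 and scored with the Dice coefficient against the case's reference
#' organ mask on the crop grid. Returns the first maximiser in scan order
#' together with the full per-window table. The search needs the reference
#' mask, so it is an evaluation/research tool, not a de-novo contouring aid.
#'
#' @param predictor A function mapping a preprocessed [seg_case()] to a soft
#'   probability array on the crop grid, or a fitted `oarseg_model`.
#' @param case A raw (unpreprocessed) [seg_case()].
#' @param spec A [roi_spec()]; its crop shape is kept, its window replaced by
#'   each candidate in turn.
#' @param grid A [window_grid()].
#' @return An object of class `window_search`: list with `best_window`
#'   ([hu_window()]), `best_sdc`, and `table` (tibble `center`, `width`,
#'   `sdc`).
#' @export
search_best_window <- function(predictor, case, spec, grid = window_grid()) {
  predict_fn <- as_predictor(predictor)
  validate_seg_case(case)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    win <- hu_window(grid$center[i], grid$width[i])
    spec_i <- roi_spec(spec$organ, crop_shape = spec$crop_shape, window = win)
    pre <- preprocess_case(case, spec_i)
    soft <- predict_fn(pre)
    if (is.null(soft) || !identical(dim(soft), dim(pre$image$voxels))) {
      abort(
        sprintf(
          "Predictor failed at window center=%g width=%g.",
          grid$center[i], grid$width[i]
        ),
        class = c("oarseg_error_predictor", "oarseg_error")
      )
    }
    bin <- (soft >= 0.5) * 1L
    dim(bin) <- dim(soft)
    as.numeric(sdc(bin, pre$organ_mask))
  }, numeric(1))
  table <- tibble::tibble(center = grid$center, width = grid$width, sdc = scores)
  best <- which.max(scores) # first maximiser in scan order
  structure(
    list(
      best_window = hu_window(grid$center[best], grid$width[best]),
      best_sdc = scores[best],
      table = table
    ),
    class = "window_search"
  )
}

#' @export
print.window_search <- function(x, ...) {
  cat(sprintf(
    "<window_search> %d windows; best center=%g width=%g (SDC %.4f)\n",
    nrow(x$table), x$best_window$center, x$best_window$width, x$best_sdc
  ))
  invisible(x)
}

#' @export
tidy.window_search <- function(x, ...) x$table

#' Compare the organ's set window with patient-specific windows
#'
#' For each case, scores the predictor under the organ's default ("set")
#' window and under the best window found by [search_best_window()], with
#' the Hausdorff distance evaluated at both, and aggregates mean and SD.
#'
#' @inheritParams search_best_window
#' @param cases List of raw [seg_case()]s.
#' @return A list with `per_case` (tibble: `case_id`, `sdc_set`, `hd_set`,
#'   `sdc_patient`, `hd_patient`, `center`, `width`) and `summary` (tibble of
#'   mean and SD per metric).
#' @export
compare_set_vs_patient_window <- function(predictor, cases, spec,
                                          grid = window_grid()) {
  if (length(cases) < 1) abort_validation("Need at least one case.")
  predict_fn <- as_predictor(predictor)
  rows <- purrr::map(cases, function(case) {
    pre <- preprocess_case(case, spec)
    soft <- predict_fn(pre)
    bin <- (soft >= 0.5) * 1L
    dim(bin) <- dim(soft)
    hd_of <- function(mask, ref) {
      if (sum(mask) == 0) NA_real_ else hausdorff_3d(mask, ref)
    }
    res <- search_best_window(predict_fn, case, spec, grid)
    spec_best <- roi_spec(
      spec$organ,
      crop_shape = spec$crop_shape,
      window = res$best_window
    )
    pre_best <- preprocess_case(case, spec_best)
    soft_best <- predict_fn(pre_best)
    bin_best <- (soft_best >= 0.5) * 1L
    dim(bin_best) <- dim(soft_best)
    tibble::tibble(
      case_id = case$case_id,
      sdc_set = as.numeric(sdc(bin, pre$organ_mask)),
      hd_set = hd_of(bin, pre$organ_mask),
      sdc_patient = res$best_sdc,
      hd_patient = hd_of(bin_best, pre_best$organ_mask),
      center = res$best_window$center,
      width = res$best_window$width
    )
  })
  per_case <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    metric = c("sdc_set", "sdc_patient", "hd_set", "hd_patient"),
    mean = vapply(
      per_case[, c("sdc_set", "sdc_patient", "hd_set", "hd_patient")],
      mean, numeric(1), na.rm = TRUE
    ),
    sd = vapply(
      per_case[, c("sdc_set", "sdc_patient", "hd_set", "hd_patient")],
      stats::sd, numeric(1), na.rm = TRUE
    )
  )
  list(per_case = per_case, summary = summary)
}
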