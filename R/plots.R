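#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_hline
#'   geom_ribbon geom_errorbar labs scale_fill_viridis_c theme_minimal
NULL

#' Plot a training log
#'
#' Train and validation loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param object An `oarseg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oarseg_fit <- function(object, ...) {
  log <- object$log
  df <- dplyr::bind_rows(
    tibble::tibble(epoch = log$epoch, loss = log$train_loss, set = "train"),
    tibble::tibble(epoch = log$epoch, loss = log$val_loss, set = "validation")
  )
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    geom_point(size = 0.8) +
    ggplot2::geom_vline(
      xintercept = object$best_epoch, linetype = "dashed", colour = "grey50"
    ) +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' Plot a patient-specific window search surface
#'
#' Dice coefficient over the centre x width grid, with the selected best
#' window marked.
#'
#' @param object A `window_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_search <- function(object, ...) {
  ggplot(object$table, aes(x = .data$center, y = .data$width, fill = .data$sdc)) +
    geom_tile() +
    geom_point(
      data = tibble::tibble(
        center = object$best_window$center, width = object$best_window$width
      ),
      aes(x = .data$center, y = .data$width),
      inherit.aes = FALSE, shape = 4, size = 3
    ) +
    scale_fill_viridis_c() +
    labs(x = "window center (HU)", y = "window width (HU)", fill = "SDC") +
    theme_minimal()
}

#' Plot an ensemble cut-off sweep
#'
#' Ensemble Dice per cut-off with the stand-alone mean (solid) and +/- 1 SD
#' band (dashed) of the individual members.
#'
#' @param object A `cutoff_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutoff_sweep <- function(object, ...) {
  m <- object$standalone_summary$mean[1]
  s <- object$standalone_summary$sd[1]
  ggplot(object$table, aes(x = .data$cutoff, y = .data$sdc)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = m, colour = "grey40") +
    geom_hline(yintercept = c(m - s, m + s), colour = "grey40",
               linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$table$cutoff) +
    labs(x = "cut-off (votes required)", y = "SDC") +
    theme_minimal()
}

#' Plot a sweep summary (set size or augmentation count)
#'
#' Mean Dice with +/- 1 SD error bars against the swept quantity.
#'
#' @param sweep A `size_sweep` or `aug_sweep`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  df <- dplyr::filter(sweep$summary, .data$metric == "sdc")
  xvar <- if ("size" %in% names(df)) "size" else "count"
  ggplot(df, aes(x = .data[[xvar]], y = .data$mean)) +
    geom_errorbar(
      aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.02 * diff(range(df[[xvar]]) + c(0, 1))
    ) +
    geom_line() +
    geom_point() +
    labs(x = xvar, y = "SDC (mean ± SD)") +
    theme_minimal()
}
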