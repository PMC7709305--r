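#' Per-voxel vote counts over an ensemble of predictions
#'
#' Counts, at every voxel, how many of the member predictions mark it
#' positive. Members must share one grid.
#'
#' @param preds List of 3D binary arrays (the members' predictions).
#' @return A 3D integer array of counts in `[0, N]`, class `vote_map`, with
#'   attribute `n_models`.
#' @export
vote <- function(preds) {
  if (length(preds) < 1) abort_validation("Need at least one prediction.")
  d <- dim(preds[[1]])
  preds <- lapply(preds, function(p) {
    if (!identical(dim(p), d)) {
      abort_validation("All ensemble predictions must share one shape.")
    }
    binary_mask(p)
  })
  counts <- Reduce(`+`, preds)
  structure(counts, class = "vote_map", n_models = length(preds))
}

#' Threshold a vote map at a cut-off
#'
#' A voxel is positive in the ensemble mask iff at least `cutoff` members
#' voted for it: cut-off 1 gives the union of the members, cut-off N their
#' intersection, and the majority cut-off (6 of 11 in the standard set-up)
#' the usual majority vote.
#'
#' @param votes A vote map from [vote()].
#' @param cutoff Integer in `[1, N]`.
#' @return A 3D binary mask array.
#' @export
threshold_votes <- function(votes, cutoff) {
  n <- attr(votes, "n_models") %||% max(votes)
  if (cutoff < 1 || cutoff > n) {
    abort_validation(sprintf("`cutoff` must be in [1, %d].", n))
  }
  out <- (unclass(votes) >= cutoff) * 1L
  dim(out) <- dim(votes)
  binary_mask(out)
}

#' Majority cut-off for an ensemble of n models
#'
#' The smallest cut-off representing a strict majority: `floor(n/2) + 1`
#' (6 for the standard 11-model ensemble).
#'
#' @param n_models Ensemble size.
#' @return Integer cut-off.
#' @export
majority_cutoff <- function(n_models) {
  as.integer(floor(n_models / 2) + 1L)
}

#' Sweep all cut-offs of an ensemble against a reference
#'
#' Evaluates the ensemble mask at every cut-off 1..N with the Dice
#' coefficient and Hausdorff distance, alongside the stand-alone baseline:
#' mean and SD of each metric over the N individual members. An empty
#' ensemble mask at a high cut-off scores Dice 0 with an undefined-flagged
#' (NA) Hausdorff distance.
#'
#' @param preds List of 3D binary member predictions.
#' @param ref Non-empty 3D binary reference mask.
#' @return An object of class `cutoff_sweep`: list with `table` (tibble
#'   `cutoff`, `sdc`, `hd`, `empty`), `standalone` (tibble `model`, `sdc`,
#'   `hd`) and `standalone_summary` (mean/SD rows).
#' @export
sweep_cutoffs <- function(preds, ref) {
  if (mask_count(ref) == 0) abort_validation("Reference mask is empty.")
  votes <- vote(preds)
  n <- attr(votes, "n_models")
  eval_mask <- function(mask) {
    if (sum(mask) == 0) {
      return(list(sdc = 0, hd = NA_real_, empty = TRUE))
    }
    list(
      sdc = as.numeric(sdc(mask, ref)),
      hd = hausdorff_3d(mask, ref), empty = FALSE
    )
  }
  rows <- purrr::map(seq_len(n), function(k) {
    m <- eval_mask(threshold_votes(votes, k))
    tibble::tibble(cutoff = k, sdc = m$sdc, hd = m$hd, empty = m$empty)
  })
  standalone <- purrr::imap(preds, function(p, i) {
    m <- eval_mask(binary_mask(p))
    tibble::tibble(model = i, sdc = m$sdc, hd = m$hd)
  })
  standalone <- dplyr::bind_rows(standalone)
  structure(
    list(
      table = dplyr::bind_rows(rows),
      standalone = standalone,
      standalone_summary = tibble::tibble(
        metric = c("sdc", "hd"),
        mean = c(mean(standalone$sdc), mean(standalone$hd, na.rm = TRUE)),
        sd = c(
          stats::sd(standalone$sdc),
          stats::sd(standalone$hd, na.rm = TRUE)
        )
      ),
      n_models = n
    ),
    class = "cutoff_sweep"
  )
}

#' @export
print.cutoff_sweep <- function(x, ...) {
  cat(sprintf(
    "<cutoff_sweep> %d models; majority cutoff %d; stand-alone mean SDC %.4f\n",
    x$n_models, majority_cutoff(x$n_models), x$standalone_summary$mean[1]
  ))
  print(x$table)
  invisible(x)
}

#' @export
tidy.cutoff_sweep <- function(x, ...) x$table
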