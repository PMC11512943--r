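#' Per-epoch variance of ensemble predictions
#'
#' The population variance (divide by the number of members) of the member
#' probabilities for each epoch — the disagreement score that drives epoch
#' rejection. It is zero exactly when all members agree and can never
#' exceed 0.25 for probabilities. The ranking of epochs is identical under
#' the sample-variance convention; the population form also behaves
#' sensibly for two-row Monte Carlo dropout tensors.
#'
#' @param tensor A `prediction_tensor` with at least 2 members.
#' @return A tibble `epoch, subject_id, variance` of class
#'   `uncertainty_scores`.
#' @export
epoch_variance <- function(tensor) {
  check_tensor(tensor)
  if (nrow(tensor) < 2) {
    stop_config("epoch variance needs at least 2 ensemble members")
  }
  m <- colMeans(tensor)
  v <- colMeans(tensor^2) - m^2
  out <- tibble(
    epoch = seq_len(ncol(tensor)),
    subject_id = attr(tensor, "epoch_subject"),
    variance = pmax(v, 0)
  )
  class(out) <- c("uncertainty_scores", class(out))
  out
}

#' Reject the most uncertain epochs
#'
#' Removes the `floor(p/100 * n)` highest-variance epochs and returns the
#' sorted indices of the kept ones. By default rejection is per subject —
#' each subject loses its own top-`p`% epochs, so per-subject voting always
#' retains each subject's most certain epochs; `pooled = TRUE` ranks all
#' epochs jointly instead. Variance ties are broken by epoch index: the
#' earlier epoch is kept.
#'
#' @param tensor A `prediction_tensor`.
#' @param scores The matching [epoch_variance()] result.
#' @param p Percentage of epochs to remove, `0 <= p < 100`.
#' @param pooled Rank epochs across all subjects instead of per subject.
#' @return Sorted integer vector of kept epoch indices.
#' @export
reject_uncertain <- function(tensor, scores, p, pooled = FALSE) {
  check_tensor(tensor)
  if (!is_scalar_number(p) || p < 0 || p >= 100) {
    stop_config("p must satisfy 0 <= p < 100")
  }
  drop_top <- function(idx) {
    n_remove <- floor(p / 100 * length(idx))
    if (n_remove == 0) return(idx)
    v <- scores$variance[idx]
    # remove the highest variance; among ties remove the later epoch first
    removal_order <- idx[order(-v, -idx)]
    setdiff(idx, removal_order[seq_len(n_remove)])
  }
  if (pooled) {
    kept <- drop_top(seq_len(ncol(tensor)))
  } else {
    subj <- attr(tensor, "epoch_subject")
    kept <- unlist(lapply(unique(subj), function(s) drop_top(which(subj == s))),
                   use.names = FALSE)
  }
  sort(kept)
}

#' Rejection curve: performance after removing uncertain epochs
#'
#' For every `p` in the grid, removes the `p`% most uncertain epochs
#' (ranked by [epoch_variance()]), re-runs the chosen voting scheme on the
#' surviving epochs, and records per-subject and per-epoch accuracy. A
#' subject whose epochs are all removed falls back to its full-epoch
#' (`p = 0`) prediction and is counted in `n_fallback`.
#'
#' @param tensor A `prediction_tensor`.
#' @param labels Data frame `subject_id, label`.
#' @param scheme `"ensemble_epoch"` or `"ensemble_subject"`.
#' @param p_grid Percentages of epochs to remove.
#' @param pooled Passed to [reject_uncertain()].
#' @return A tibble `p_removed, per_subject_accuracy, per_epoch_accuracy,
#'   n_epochs_kept, n_fallback` of class `rejection_curve`.
#' @export
rejection_curve <- function(tensor, labels,
                            scheme = c("ensemble_epoch", "ensemble_subject"),
                            p_grid = c(0, 10, 25, 50, 75, 90),
                            pooled = FALSE) {
  check_tensor(tensor)
  scheme <- match.arg(scheme)
  if (length(p_grid) == 0) stop_config("p_grid must be non-empty")
  labels <- as_tibble(labels)
  lab_map <- setNames(labels$label, labels$subject_id)
  subj <- attr(tensor, "epoch_subject")
  subjects <- unique(subj)
  if (any(!subjects %in% names(lab_map))) {
    stop_input("labels are missing for some subjects in the tensor")
  }
  scores <- epoch_variance(tensor)
  vote_fun <- if (scheme == "ensemble_epoch") ensemble_epoch_vote else ensemble_subject_vote
  full_pred <- vapply(subjects, function(s) vote_fun(tensor, s), 0L)

  rows <- lapply(sort(p_grid), function(p) {
    kept <- reject_uncertain(tensor, scores, p, pooled)
    n_fallback <- 0L
    preds <- vapply(subjects, function(s) {
      cols <- intersect(which(subj == s), kept)
      if (length(cols) == 0) {
        n_fallback <<- n_fallback + 1L
        full_pred[[s]]
      } else {
        vote_fun(tensor, s, cols = cols)
      }
    }, 0L)
    epoch_acc <- if (length(kept) > 0) {
      per_epoch_accuracy(colMeans(tensor[, kept, drop = FALSE]),
                         as.integer(lab_map[subj[kept]]))
    } else {
      NA_real_
    }
    tibble(
      p_removed = p,
      per_subject_accuracy = 100 * mean(preds == lab_map[subjects]),
      per_epoch_accuracy = epoch_acc,
      n_epochs_kept = length(kept),
      n_fallback = n_fallback
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scheme") <- scheme
  attr(out, "pooled") <- pooled
  class(out) <- c("rejection_curve", class(out))
  out
}

#' Relative error decrease
#'
#' The percentage by which the classification error shrank:
#' `((100 - acc_before) - (100 - acc_after)) / (100 - acc_before) * 100`.
#' Undefined when the error before removal is already zero; such cells are
#' returned as `NA` and excluded from aggregation.
#'
#' @param acc_before,acc_after Accuracies in percent.
#' @return Error decrease in percent (negative when performance degraded),
#'   `NA` when `acc_before == 100`.
#' @export
error_decrease <- function(acc_before, acc_after) {
  if (any(acc_before < 0 | acc_before > 100 | acc_after < 0 | acc_after > 100)) {
    stop_input("accuracies must lie in [0, 100]")
  }
  out <- ((100 - acc_before) - (100 - acc_after)) / (100 - acc_before) * 100
  out[acc_before == 100] <- NA_real_
  out
}

#' Error-decrease summary across ensembles and folds
#'
#' Aggregates per-(ensemble, fold, p) error decreases into the three
#' summary rows of the uncertainty analysis: the average over all
#' (ensemble, fold) cells, the mean over ensembles of each ensemble's
#' per-fold maximum, and the global maximum — one column per rejection
#' percentage (reported alongside the equivalent percentage of kept
#' epochs, `100 - p`). `NA` cells (zero error before removal) are flagged
#' and excluded.
#'
#' @param decreases A data frame with columns `ensemble, fold, p_removed,
#'   error_decrease`.
#' @return A tibble `p_removed, pct_kept, avg, avg_max, max, n_undefined`
#'   of class `error_decrease_summary`.
#' @export
summarize_error_decrease <- function(decreases) {
  decreases <- as_tibble(decreases)
  need <- c("ensemble", "fold", "p_removed", "error_decrease")
  if (!all(need %in% names(decreases))) {
    stop_input(sprintf("decreases must have columns %s",
                       paste(need, collapse = ", ")))
  }
  if (nrow(decreases) == 0) stop_input("no error decreases to summarize")
  out <- decreases |>
    dplyr::group_by(.data$p_removed) |>
    dplyr::summarise(
      pct_kept = 100 - .data$p_removed[1],
      avg = mean(.data$error_decrease, na.rm = TRUE),
      avg_max = mean(vapply(
        split(.data$error_decrease, .data$ensemble),
        function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), 0),
        na.rm = TRUE),
      max = if (all(is.na(.data$error_decrease))) NA_real_
            else max(.data$error_decrease, na.rm = TRUE),
      n_undefined = sum(is.na(.data$error_decrease)),
      .groups = "drop"
    )
  class(out) <- c("error_decrease_summary", class(out))
  out
}
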