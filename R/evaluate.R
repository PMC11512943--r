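#' Stratified fold assignment
#'
#' Randomly partitions subjects into `n_folds` folds, stratified by class so
#' per-fold class counts differ by at most one. Splits are meant to be
#' generated once per study and reused across all experiments.
#'
#' @param subjects A data frame with columns `subject_id` and `label`
#'   (binary 0/1).
#' @param n_folds Number of folds.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A tibble `subject_id, label, fold` of class `fold_split`.
#' @export
make_folds <- function(subjects, n_folds = 5L, seed = 1L) {
  subjects <- as_tibble(subjects)
  if (!all(c("subject_id", "label") %in% names(subjects))) {
    stop_input("subjects must have columns subject_id and label")
  }
  counts <- table(factor(subjects$label, levels = c(0, 1)))
  if (any(counts < n_folds)) {
    stop_input(sprintf(
      "each class needs at least %d subjects for %d folds (have %s)",
      n_folds, n_folds, paste(counts, collapse = "/")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 11L))
  fold <- integer(nrow(subjects))
  for (cls in c(0, 1)) {
    idx <- which(subjects$label == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  out <- subjects
  out$fold <- fold
  class(out) <- c("fold_split", class(out))
  attr(out, "n_folds") <- as.integer(n_folds)
  out
}

#' Cross-validation rotations
#'
#' Expands a fold split into its rotations: rotation `r` tests on fold `r`,
#' validates on the next fold (cyclically), and trains on the remaining
#' folds. Test folds across rotations are disjoint and jointly cover every
#' subject, so each subject is tested exactly once.
#'
#' @param split A [make_folds()] result.
#' @return A list of rotations, each with character vectors `train`,
#'   `validation`, `test` of subject ids, and `test_fold`.
#' @export
rotations <- function(split) {
  if (!inherits(split, "fold_split")) stop_input("expected a fold_split")
  n_folds <- attr(split, "n_folds")
  lapply(seq_len(n_folds), function(r) {
    val_fold <- (r %% n_folds) + 1L
    list(
      test_fold = r,
      test = split$subject_id[split$fold == r],
      validation = split$subject_id[split$fold == val_fold],
      train = split$subject_id[!split$fold %in% c(r, val_fold)]
    )
  })
}

#' Per-epoch accuracy
#'
#' Fraction of epochs whose thresholded prediction (probability >= 0.5 is
#' class 1) matches the label, as a percentage.
#'
#' @param probs Class-1 probabilities per epoch.
#' @param labels Binary labels per epoch.
#' @param threshold Decision threshold.
#' @return Accuracy in percent.
#' @export
per_epoch_accuracy <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop_input("no epochs to score")
  if (length(probs) != length(labels)) {
    stop_input("probs and labels differ in length")
  }
  100 * mean((probs >= threshold) == (labels == 1))
}

#' Majority vote over one subject's epochs
#'
#' Each epoch is classified at the threshold; the more frequent class wins.
#' A tied vote is broken by the mean probability against 0.5, and an exact
#' mean of 0.5 resolves to class 1.
#'
#' @param probs Class-1 probabilities of the subject's epochs.
#' @param threshold Decision threshold.
#' @return Predicted class, 0 or 1.
#' @export
subject_majority <- function(probs, threshold = 0.5) {
  if (length(probs) == 0) stop_input("subject has no epochs")
  votes1 <- sum(probs >= threshold)
  votes0 <- length(probs) - votes1
  if (votes1 > votes0) return(1L)
  if (votes0 > votes1) return(0L)
  if (mean(probs) >= 0.5) 1L else 0L
}

check_tensor <- function(tensor) {
  if (!inherits(tensor, "prediction_tensor")) {
    stop_input("expected a prediction_tensor")
  }
  invisible(tensor)
}

tensor_subject_cols <- function(tensor, subject) {
  cols <- which(attr(tensor, "epoch_subject") == subject)
  if (length(cols) == 0) {
    stop_input(sprintf("subject %s has no epochs in the tensor", subject))
  }
  cols
}

#' Ensemble-Subject vote
#'
#' Each ensemble member first performs its own majority vote over the
#' subject's epochs; the most frequent member verdict is the subject
#' prediction. A tie between member verdicts is resolved by the
#' ensemble-mean probability over the subject's epochs against 0.5 (and
#' exactly 0.5 resolves to class 1).
#'
#' @param tensor A `prediction_tensor` (members x epochs).
#' @param subject Subject id present in the tensor.
#' @param cols Optional explicit epoch columns (used internally when epochs
#'   have been rejected).
#' @return Predicted class, 0 or 1.
#' @export
ensemble_subject_vote <- function(tensor, subject, cols = NULL) {
  check_tensor(tensor)
  cols <- cols %||% tensor_subject_cols(tensor, subject)
  verdicts <- apply(tensor[, cols, drop = FALSE], 1, subject_majority)
  v1 <- sum(verdicts == 1)
  v0 <- length(verdicts) - v1
  if (v1 > v0) return(1L)
  if (v0 > v1) return(0L)
  if (mean(tensor[, cols]) >= 0.5) 1L else 0L
}

#' Ensemble-Epoch vote
#'
#' The member probabilities are averaged per epoch; the averaged
#' predictions are thresholded and the within-subject majority (with the
#' same tie rules as [subject_majority()]) gives the subject prediction.
#'
#' @inheritParams ensemble_subject_vote
#' @return Predicted class, 0 or 1.
#' @export
ensemble_epoch_vote <- function(tensor, subject, cols = NULL) {
  check_tensor(tensor)
  cols <- cols %||% tensor_subject_cols(tensor, subject)
  subject_majority(colMeans(tensor[, cols, drop = FALSE]))
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen class-1 score exceeds a randomly
#' chosen class-0 score, ties counting one half — the rank-sum estimator,
#' identical to exhaustive pair counting.
#'
#' @param probs Scores.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probs, labels) {
  y <- labels == 1
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop_input("AUC requires both classes among the labels")
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a prediction tensor on one test fold
#'
#' Computes per-epoch accuracy (ensemble-mean probabilities against epoch
#' labels), per-subject accuracy under the chosen aggregation scheme, and
#' epoch-level AUC.
#'
#' @param tensor A `prediction_tensor`.
#' @param labels A data frame `subject_id, label` covering the tensor's
#'   subjects.
#' @param scheme `"ensemble_epoch"` or `"ensemble_subject"`.
#' @return A one-row tibble `scheme, per_epoch_accuracy,
#'   per_subject_accuracy, auc, n_subjects, n_epochs`.
#' @export
evaluate_tensor <- function(tensor, labels,
                            scheme = c("ensemble_epoch", "ensemble_subject")) {
  check_tensor(tensor)
  scheme <- match.arg(scheme)
  labels <- as_tibble(labels)
  subj <- attr(tensor, "epoch_subject")
  lab_map <- setNames(labels$label, labels$subject_id)
  if (any(!unique(subj) %in% names(lab_map))) {
    stop_input("labels are missing for some subjects in the tensor")
  }
  epoch_labels <- as.integer(lab_map[subj])
  mean_probs <- colMeans(tensor)
  vote_fun <- if (scheme == "ensemble_epoch") ensemble_epoch_vote else ensemble_subject_vote
  subjects <- unique(subj)
  preds <- vapply(subjects, function(s) vote_fun(tensor, s), 0L)
  tibble(
    scheme = scheme,
    per_epoch_accuracy = per_epoch_accuracy(mean_probs, epoch_labels),
    per_subject_accuracy = 100 * mean(preds == lab_map[subjects]),
    auc = auc_score(mean_probs, epoch_labels),
    n_subjects = length(subjects),
    n_epochs = length(subj)
  )
}

#' Summarize per-fold results as mean and 95% confidence interval
#'
#' For every numeric metric column, computes the across-fold mean and the
#' Student-t 95% half-width (`t[0.975, n-1] * sd / sqrt(n)`), grouped by
#' any non-numeric columns (e.g. `scheme`).
#'
#' @param fold_results A data frame with one row per fold; must contain a
#'   `fold` column.
#' @return A tibble `metric, mean, ci95_halfwidth, n_folds` (plus grouping
#'   columns), of class `cv_summary`.
#' @export
summarize_cv <- function(fold_results) {
  fold_results <- as_tibble(fold_results)
  if (!"fold" %in% names(fold_results)) {
    stop_input("fold_results must contain a fold column")
  }
  if (dplyr::n_distinct(fold_results$fold) < 2) {
    stop_input("need at least two folds to summarize")
  }
  metric_cols <- setdiff(
    names(fold_results)[vapply(fold_results, is.numeric, TRUE)],
    c("fold", "n_subjects", "n_epochs"))
  group_cols <- setdiff(names(fold_results),
                        c(metric_cols, "fold", "n_subjects", "n_epochs"))
  long <- tidyr::pivot_longer(fold_results, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci95_halfwidth = qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n()),
      n_folds = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("cv_summary", class(out))
  out
}
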