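test_that("stratified folds balance classes and cover every subject once", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", 1:1780),
    label = rep(c(0L, 1L), each = 890)
  )
  split <- make_folds(subjects, 5, seed = 3)
  sizes <- table(split$fold)
  expect_true(all(sizes == 356))
  per_class <- table(split$fold, split$label)
  expect_true(all(per_class == 178))

  expect_identical(split, make_folds(subjects, 5, seed = 3))
  expect_false(identical(split$fold, make_folds(subjects, 5, seed = 4)$fold))

  small <- tibble::tibble(subject_id = sprintf("T%02d", 1:10),
                          label = rep(0:1, 5))
  ssplit <- make_folds(small, 5, seed = 1)
  expect_true(all(table(ssplit$fold) == 2))
  expect_true(all(table(ssplit$fold, ssplit$label) == 1))

  few <- tibble::tibble(subject_id = sprintf("U%02d", 1:8),
                        label = c(rep(0L, 4), rep(1L, 4)))
  expect_error(make_folds(few, 5), class = "eegensemble_input_error")
})

test_that("fold stratification stays within one subject per class", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(23:157, 1)
    subjects <- tibble::tibble(subject_id = sprintf("R%04d", seq_len(n)),
                               label = rbinom(n, 1, 0.5))
    if (min(table(factor(subjects$label, levels = 0:1))) < 5) next
    split <- make_folds(subjects, 5, seed = i)
    counts <- table(split$fold, split$label)
    expect_lte(max(counts[, 1]) - min(counts[, 1]), 1)
    expect_lte(max(counts[, 2]) - min(counts[, 2]), 1)
  }
})

test_that("rotations are disjoint, exhaustive, and follow the convention", {
  subjects <- tibble::tibble(subject_id = sprintf("S%03d", 1:50),
                             label = rep(0:1, 25))
  split <- make_folds(subjects, 5, seed = 6)
  rots <- rotations(split)
  expect_length(rots, 5)
  test_sets <- lapply(rots, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), sort(subjects$subject_id))
  expect_equal(sum(lengths(test_sets)), 50)  # pairwise disjoint + exhaustive
  for (r in seq_along(rots)) {
    rot <- rots[[r]]
    expect_length(intersect(rot$train, rot$test), 0)
    expect_length(intersect(rot$train, rot$validation), 0)
    expect_length(intersect(rot$validation, rot$test), 0)
    expect_equal(sort(c(rot$train, rot$validation, rot$test)),
                 sort(subjects$subject_id))
    expect_equal(rot$test_fold, r)
    expect_setequal(rot$test, split$subject_id[split$fold == r])
  }
})

test_that("per-epoch accuracy applies the stated threshold and tie rule", {
  expect_equal(per_epoch_accuracy(c(0.9, 0.1), c(1, 0)), 100)
  expect_equal(per_epoch_accuracy(c(0.9, 0.9), c(1, 0)), 50)
  expect_equal(per_epoch_accuracy(c(0.5), c(1)), 100)  # 0.5 predicts class 1
  expect_equal(per_epoch_accuracy(c(0.5), c(0)), 0)
  expect_error(per_epoch_accuracy(numeric(0), numeric(0)),
               class = "eegensemble_input_error")
})

test_that("subject majority voting follows the stated tie rules", {
  expect_equal(subject_majority(c(rep(0.9, 25), rep(0.1, 15))), 1L)
  expect_equal(subject_majority(c(rep(0.9, 20), rep(0.1, 20)) + 0.0), 1L)
  expect_equal(subject_majority(rep(c(0.95, 0.21), 20)), 1L)  # mean 0.58 tie
  expect_equal(subject_majority(rep(c(0.6, 0.1), 20)), 0L)    # mean 0.35 tie
  expect_equal(subject_majority(0.3), 0L)
  expect_equal(subject_majority(0.5), 1L)
})

test_that("ensemble votes match exhaustive truth tables including ties", {
  grids <- list(c(0.3, 0.7), c(0.2, 0.5))
  set.seed(99)
  for (grid in grids) {
    for (n_members in 1:3) {
      for (n_epochs in c(1L, 2L, 4L, 5L)) {
        combos <- as.matrix(expand.grid(rep(list(grid), n_members * n_epochs)))
        if (nrow(combos) > 2048) {
          combos <- combos[sample(nrow(combos), 2048), , drop = FALSE]
        }
        mismatches <- 0L
        for (i in seq_len(nrow(combos))) {
          mat <- matrix(combos[i, ], n_members, n_epochs)
          tensor <- prediction_tensor(mat, rep("A", n_epochs))
          if (!identical(ensemble_subject_vote(tensor, "A"),
                         oracle_ensemble_subject(mat)) ||
              !identical(ensemble_epoch_vote(tensor, "A"),
                         oracle_ensemble_epoch(mat))) {
            mismatches <- mismatches + 1L
          }
        }
        expect_equal(mismatches, 0L)
      }
    }
  }
})

test_that("single-member ensembles reduce to the plain subject majority", {
  set.seed(2)
  for (i in 1:20) {
    probs <- runif(7)
    tensor <- prediction_tensor(matrix(probs, 1), rep("A", 7))
    expect_equal(ensemble_epoch_vote(tensor, "A"), subject_majority(probs))
    expect_equal(ensemble_subject_vote(tensor, "A"), subject_majority(probs))
  }
  # identical members agree with one member under both schemes
  for (i in 1:10) {
    probs <- runif(5)
    mat <- rbind(probs, probs, probs)
    tensor <- prediction_tensor(mat, rep("A", 5))
    expect_equal(ensemble_epoch_vote(tensor, "A"), subject_majority(probs))
    expect_equal(ensemble_subject_vote(tensor, "A"), subject_majority(probs))
  }
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)

  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    probs <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_score(probs, labels), oracle_auc(probs, labels))
  }

  # invariance under strictly monotone transforms
  probs <- runif(30)
  labels <- c(0, 1, rbinom(28, 1, 0.5))
  expect_equal(auc_score(plogis(3 * probs - 1), labels),
               auc_score(probs, labels))

  # label-independent scores sit near one half
  set.seed(11)
  expect_lt(abs(auc_score(runif(4000), rbinom(4000, 1, 0.5)) - 0.5), 0.05)

  expect_error(auc_score(runif(5), rep(1, 5)),
               class = "eegensemble_input_error")
})

test_that("cross-validation summaries use the Student-t 95% interval", {
  res <- tibble::tibble(fold = 1:5,
                        per_subject_accuracy = c(88, 90, 92, 90, 90))
  s <- summarize_cv(res)
  expect_equal(s$mean, 90)
  expect_equal(s$ci95_halfwidth, qt(0.975, 4) * sqrt(2) / sqrt(5))

  same <- tibble::tibble(fold = 1:5, per_subject_accuracy = rep(85, 5))
  expect_equal(summarize_cv(same)$ci95_halfwidth, 0)

  shuffled <- res[c(3, 1, 5, 2, 4), ]
  expect_equal(summarize_cv(shuffled)$mean, s$mean)

  expect_error(summarize_cv(res[1, ]), class = "eegensemble_input_error")
})

test_that("evaluate_tensor combines the three metrics coherently", {
  mat <- rbind(c(0.9, 0.8, 0.2, 0.1), c(0.7, 0.9, 0.3, 0.2))
  tensor <- prediction_tensor(mat, c("A", "A", "B", "B"))
  labels <- tibble::tibble(subject_id = c("A", "B"), label = c(1L, 0L))
  ev <- evaluate_tensor(tensor, labels, "ensemble_epoch")
  expect_equal(ev$per_subject_accuracy, 100)
  expect_equal(ev$per_epoch_accuracy, 100)
  expect_equal(ev$auc, 1)
  expect_equal(ev$n_subjects, 2L)
  expect_error(evaluate_tensor(tensor, labels[1, ], "ensemble_epoch"),
               class = "eegensemble_input_error")
})
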