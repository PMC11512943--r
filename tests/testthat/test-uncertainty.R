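test_that("epoch variance matches a brute-force oracle and closed forms", {
  # closed forms
  expect_equal(epoch_variance(
    prediction_tensor(matrix(c(0.7, 0.7, 0.7), 3), "A"))$variance, 0)
  expect_equal(epoch_variance(
    prediction_tensor(matrix(c(0, 1), 2), "A"))$variance, 0.25)

  t3 <- prediction_tensor(cbind(c(0.5, 0.5, 0.5), c(0.1, 0.5, 0.9)),
                          c("A", "A"))
  v <- epoch_variance(t3)$variance
  expect_gt(v[2], v[1])

  # brute-force equivalence on many random tensors
  set.seed(17)
  worst <- 0
  for (i in 1:1000) {
    m <- sample(2:8, 1)
    e <- sample(1:12, 1)
    mat <- matrix(runif(m * e), m, e)
    tensor <- prediction_tensor(mat, rep("A", e))
    worst <- max(worst, max(abs(epoch_variance(tensor)$variance -
                                  oracle_epoch_variance(mat))))
  }
  expect_lte(worst, 1e-12)

  expect_error(epoch_variance(prediction_tensor(matrix(0.5, 1, 3),
                                                rep("A", 3))),
               class = "eegensemble_config_error")
})

test_that("rejection removes the floor-count of highest-variance epochs", {
  set.seed(3)
  tensor <- random_tensor(4, ns = 1, ne = 40)
  scores <- epoch_variance(tensor)
  expect_length(reject_uncertain(tensor, scores, 10), 36)
  expect_length(reject_uncertain(tensor, scores, 25), 30)
  expect_length(reject_uncertain(tensor, scores, 0), 40)
  expect_error(reject_uncertain(tensor, scores, 100),
               class = "eegensemble_config_error")
  expect_error(reject_uncertain(tensor, scores, -5),
               class = "eegensemble_config_error")

  # the removed epochs are exactly the highest-variance ones
  kept <- reject_uncertain(tensor, scores, 25)
  removed <- setdiff(1:40, kept)
  expect_gte(min(scores$variance[removed]), max(scores$variance[kept]))
})

test_that("kept sets are nested over the rejection grid", {
  set.seed(9)
  tensor <- random_tensor(3, ns = 5, ne = 12)
  scores <- epoch_variance(tensor)
  for (pooled in c(FALSE, TRUE)) {
    grid <- c(10, 25, 50, 75, 90)
    kept <- lapply(grid, function(p) {
      reject_uncertain(tensor, scores, p, pooled = pooled)
    })
    for (i in seq_len(length(grid) - 1)) {
      expect_true(all(kept[[i + 1]] %in% kept[[i]]))
    }
  }
})

test_that("variance ties are broken by keeping the earlier epoch", {
  mat <- rbind(rep(0.4, 6), rep(0.6, 6))  # identical variance everywhere
  tensor <- prediction_tensor(mat, rep("A", 6))
  scores <- epoch_variance(tensor)
  expect_equal(reject_uncertain(tensor, scores, 50), 1:3)
})

test_that("per-subject rejection removes each subject's own fraction", {
  # subject A has uniformly high variance, B agrees perfectly
  mat <- cbind(matrix(c(0.1, 0.9), 2, 4), matrix(0.8, 2, 4))
  tensor <- prediction_tensor(mat, rep(c("A", "B"), each = 4))
  scores <- epoch_variance(tensor)
  kept <- reject_uncertain(tensor, scores, 50)
  expect_length(intersect(kept, 1:4), 2)  # A keeps half
  expect_length(intersect(kept, 5:8), 2)  # B keeps half despite zero variance
  pooled <- reject_uncertain(tensor, scores, 50, pooled = TRUE)
  expect_equal(pooled, 5:8)  # pooled ranking removes all of A instead
})

test_that("member permutation changes neither variance nor votes", {
  set.seed(23)
  tensor <- random_tensor(5, ns = 4, ne = 6)
  perm <- sample(5)
  permuted <- prediction_tensor(unclass(tensor)[perm, ],
                                attr(tensor, "epoch_subject"))
  expect_equal(epoch_variance(permuted)$variance,
               epoch_variance(tensor)$variance)
  for (s in unique(attr(tensor, "epoch_subject"))) {
    expect_equal(ensemble_subject_vote(permuted, s),
                 ensemble_subject_vote(tensor, s))
    expect_equal(ensemble_epoch_vote(permuted, s),
                 ensemble_epoch_vote(tensor, s))
  }
})

test_that("rejection curves improve when disagreement marks wrong epochs", {
  # fixture: per subject, 4 of 10 epochs are both wrongly predicted and
  # high-variance; the rest are confidently correct
  set.seed(31)
  ns <- 10
  labels <- tibble::tibble(subject_id = sprintf("S%02d", 1:ns),
                           label = rep(0:1, length.out = ns))
  cols <- list()
  subj <- character(0)
  for (i in seq_len(ns)) {
    lab <- labels$label[i]
    good <- matrix(rep(ifelse(lab == 1, 0.85, 0.15), 3 * 6) +
                     rnorm(18, 0, 0.02), 3, 6)
    wrong_centre <- ifelse(lab == 1, 0.25, 0.75)
    bad <- rbind(rep(wrong_centre - 0.2, 4), rep(wrong_centre, 4),
                 rep(wrong_centre + 0.2, 4)) +
      matrix(rnorm(12, 0, 0.01), 3, 4)
    cols[[i]] <- cbind(good, bad)
    subj <- c(subj, rep(labels$subject_id[i], 10))
  }
  tensor <- prediction_tensor(pmin(pmax(do.call(cbind, cols), 0), 1), subj)
  curve <- rejection_curve(tensor, labels, "ensemble_epoch",
                           p_grid = c(0, 10, 25, 50, 75, 90))
  expect_s3_class(curve, "rejection_curve")
  expect_equal(nrow(curve), 6)
  acc0 <- curve$per_subject_accuracy[curve$p_removed == 0]
  acc50 <- curve$per_subject_accuracy[curve$p_removed == 50]
  expect_gte(acc50, acc0)
  expect_equal(acc50, 100)  # all wrong epochs fall in the top half variance
})

test_that("a zero-variance tensor yields a flat rejection curve", {
  mat <- matrix(rep(c(0.8, 0.8, 0.2, 0.2), each = 2), 2)
  tensor <- prediction_tensor(mat, rep(c("A", "B"), each = 2))
  labels <- tibble::tibble(subject_id = c("A", "B"), label = c(1L, 0L))
  curve <- rejection_curve(tensor, labels, "ensemble_epoch",
                           p_grid = c(0, 50, 90))
  expect_equal(length(unique(curve$per_subject_accuracy)), 1)
  expect_error(rejection_curve(tensor, labels, p_grid = numeric(0)),
               class = "eegensemble_config_error")
})

test_that("disagreement unrelated to correctness leaves epoch accuracy unchanged", {
  # Monte Carlo: variance is assigned independently of whether the epoch's
  # mean prediction is correct, so removal cannot bias which epochs survive
  # and expected per-epoch accuracy is unchanged. (Per-subject majority
  # accuracy is excluded here on purpose: halving the number of epochs per
  # subject changes the majority vote's sampling error even under fully
  # label-agnostic removal.)
  set.seed(77)
  diffs <- replicate(200, {
    ns <- 15
    labels <- tibble::tibble(subject_id = sprintf("S%02d", 1:ns),
                             label = rbinom(ns, 1, 0.5))
    cols <- list()
    subj <- character(0)
    for (i in seq_len(ns)) {
      lab <- labels$label[i]
      correct <- rbinom(8, 1, 0.7)
      centre <- ifelse(correct == 1,
                       ifelse(lab == 1, 0.7, 0.3),
                       ifelse(lab == 1, 0.3, 0.7))
      # continuous spreads: exact variance ties would be broken by floating-
      # point noise that correlates with the centre, biasing the fixture
      spread <- runif(8, 0.02, 0.28)
      cols[[i]] <- rbind(centre - spread, centre, centre + spread)
      subj <- c(subj, rep(labels$subject_id[i], 8))
    }
    tensor <- prediction_tensor(pmin(pmax(do.call(cbind, cols), 0), 1), subj)
    curve <- rejection_curve(tensor, labels, "ensemble_epoch",
                             p_grid = c(0, 50))
    diff(curve$per_epoch_accuracy)
  })
  expect_lt(abs(mean(diffs)), 1.5)  # percentage points, within MC noise
})

test_that("subjects emptied by pooled rejection fall back to p = 0", {
  # per-subject rejection with floor counts can never empty a subject
  # (floor(p/100 * n) < n for p < 100); pooled ranking can
  mat <- cbind(matrix(c(0.1, 0.9), 2, 2), matrix(0.9, 2, 6))
  tensor <- prediction_tensor(mat, c("A", "A", rep("B", 6)))
  labels <- tibble::tibble(subject_id = c("A", "B"), label = c(1L, 1L))
  scores <- epoch_variance(tensor)
  # per subject at p = 90: A keeps 2 - floor(1.8) = 1, B keeps 6 - floor(5.4) = 1
  expect_length(reject_uncertain(tensor, scores, 90), 2)

  curve <- rejection_curve(tensor, labels, "ensemble_epoch",
                           p_grid = c(0, 50), pooled = TRUE)
  row50 <- curve[curve$p_removed == 50, ]
  expect_equal(row50$n_fallback, 1L)
  expect_equal(row50$per_subject_accuracy,
               curve$per_subject_accuracy[curve$p_removed == 0])
})

test_that("error decrease follows the stated formula and flags zero error", {
  expect_equal(error_decrease(90, 95), 50)
  expect_equal(error_decrease(90, 90), 0)
  expect_equal(error_decrease(86.6, 90.9), (13.4 - 9.1) / 13.4 * 100)
  expect_equal(round(error_decrease(86.6, 90.9), 2), 32.09)
  expect_lt(error_decrease(90, 85), 0)
  expect_true(is.na(error_decrease(100, 99)))
  expect_error(error_decrease(104, 90), class = "eegensemble_input_error")
})

test_that("error-decrease summaries aggregate avg, avg-max and max", {
  d <- tibble::tibble(
    ensemble = rep(c("e1", "e2"), each = 2),
    fold = rep(1:2, 2),
    p_removed = 50,
    error_decrease = c(5, 10, 15, 20)
  )
  s <- summarize_error_decrease(d)
  expect_equal(s$avg, 12.5)
  expect_equal(s$avg_max, 15)   # mean of per-ensemble maxima {10, 20}
  expect_equal(s$max, 20)
  expect_equal(s$pct_kept, 50)

  single <- tibble::tibble(ensemble = "e1", fold = 1, p_removed = 10,
                           error_decrease = 7)
  s1 <- summarize_error_decrease(single)
  expect_equal(c(s1$avg, s1$avg_max, s1$max), c(7, 7, 7))

  const <- tibble::tibble(ensemble = rep(c("a", "b"), 3), fold = rep(1:3, 2),
                          p_removed = 25, error_decrease = 4)
  sc <- summarize_error_decrease(const)
  expect_equal(c(sc$avg, sc$avg_max, sc$max), c(4, 4, 4))

  with_na <- dplyr::bind_rows(d, tibble::tibble(
    ensemble = "e3", fold = 1, p_removed = 50, error_decrease = NA_real_))
  sna <- summarize_error_decrease(with_na)
  expect_equal(sna$n_undefined, 1L)
  expect_equal(sna$avg, 12.5)
})
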