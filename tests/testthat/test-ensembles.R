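tr <- toy_epochs(20, "train", seed = 1)
va <- toy_epochs(8, "validation", seed = 2)
te <- toy_epochs(6, "test", seed = 3)
quick_cfg <- toy_config(max_iterations = 6L)

test_that("weight-randomization ensembles differ only in their initial draw", {
  ens <- build_weight_ensemble(toy_spec(seed = 7), "uniform", n = 3,
                               tr, va, quick_cfg)
  expect_s3_class(ens, "eeg_ensemble")
  expect_length(ens, 3)
  inits <- lapply(ens, function(m) {
    eegensemble:::net_params(build_model(m$spec, 4, 50)$net)
  })
  expect_false(identical(inits[[1]], inits[[2]]))
  expect_false(identical(inits[[2]], inits[[3]]))
  for (m in ens) {
    expect_equal(m$spec$init_scheme, "random_uniform")
    sp <- m$spec; sp$seed <- 0L; sp$init_scheme <- "x"
    sp0 <- toy_spec(seed = 7); sp0$seed <- 0L; sp0$init_scheme <- "x"
    expect_identical(sp, sp0)  # members differ only in seed / init fields
  }
  expect_error(build_weight_ensemble(toy_spec(), "uniform", n = 1, tr, va,
                                     quick_cfg),
               class = "eegensemble_config_error")
})

test_that("members of a weight ensemble all fit the separable toy task", {
  ens <- build_weight_ensemble(toy_spec(seed = 7), "normal", n = 3,
                               tr, va, toy_config())
  ds <- as_eeg_dataset(tr)
  for (m in ens) {
    p <- predict_proba(m, ds)
    expect_gte(mean((p >= 0.5) == (ds$y == 1)), 0.95)
  }
})

test_that("depth ensembles follow the requested depth list", {
  ens <- build_depth_ensemble(toy_spec(seed = 3), depths = c(2L, 4L, 6L),
                              tr, va, quick_cfg)
  expect_length(ens, 3)
  expect_equal(vapply(ens, `[[`, 0L, "depth"), c(2L, 4L, 6L))
  counts <- vapply(ens, `[[`, 0, "n_params")
  expect_true(all(diff(counts) > 0))

  single <- build_depth_ensemble(toy_spec(seed = 3), depths = 4L,
                                 tr, va, quick_cfg)
  expect_length(single, 1)
  expect_error(build_depth_ensemble(toy_spec(), depths = c(3L), tr, va,
                                    quick_cfg),
               class = "eegensemble_config_error")
})

test_that("ensemble prediction yields a valid members-by-epochs tensor", {
  ens <- build_weight_ensemble(toy_spec(seed = 7), "uniform", n = 3,
                               tr, va, quick_cfg)
  tensor <- ensemble_predict(ens, te)
  expect_s3_class(tensor, "prediction_tensor")
  expect_equal(dim(tensor), c(3, 12))
  expect_true(all(tensor >= 0 & tensor <= 1))
  expect_identical(tensor, ensemble_predict(ens, te))

  # per-epoch ensemble mean lies inside the member envelope
  expect_true(all(colMeans(tensor) <= apply(tensor, 2, max) + 1e-12))
  expect_true(all(colMeans(tensor) >= apply(tensor, 2, min) - 1e-12))

  # identical members produce identical rows
  twin <- eegensemble:::new_ensemble(list(ens[[1]], ens[[1]]), "model_pool")
  t2 <- ensemble_predict(twin, te)
  expect_equal(t2[1, ], t2[2, ])

  long <- tidy(tensor)
  expect_equal(nrow(long), 3 * 12)
})

test_that("Monte Carlo dropout behaves like a seeded stochastic ensemble", {
  tm <- toy_trained(ads = TRUE)
  t1 <- mcd_predict(tm, te, n_forward = 10, seed = 4)
  t2 <- mcd_predict(tm, te, n_forward = 10, seed = 4)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(10, 12))

  # ambiguous inputs keep the head away from sigmoid saturation, so the
  # dropout masks disperse the passes on essentially every epoch
  set.seed(55)
  amb <- toy_epochs(10, "test", seed = 55)
  for (i in 1:2) amb[[i]]$data <- amb[[i]]$data * 0.02
  ta <- mcd_predict(tm, amb, n_forward = 10, seed = 4)
  v <- epoch_variance(ta)$variance
  expect_gte(mean(v > 0), 0.9)  # dropout at 0.5 disperses the passes

  # with every dropout rate at zero the passes collapse to one prediction
  zspec <- model_spec("eegnet", seed = 2,
                      eegnet = list(f1 = 2, d = 2, f2 = 3,
                                    temporal_kernel = 7, separable_kernel = 5,
                                    pool1 = 2, pool2 = 2, block_dropout = 0))
  zm <- train_model(build_model(zspec, 4, 50), tr, va, quick_cfg)
  tz <- mcd_predict(zm, te, n_forward = 5, seed = 1)
  expect_equal(max(epoch_variance(tz)$variance), 0)

  plain <- toy_trained()
  expect_error(mcd_predict(plain, te), class = "eegensemble_config_error")
  expect_error(mcd_predict(tm, te, n_forward = 1),
               class = "eegensemble_config_error")
})

test_that("the MCD mean stabilizes as forward passes increase", {
  tm <- toy_trained(ads = TRUE)
  amb <- toy_epochs(6, "test", seed = 56)
  for (i in 1:2) amb[[i]]$data <- amb[[i]]$data * 0.02
  mean_of <- function(n_forward, seed) {
    colMeans(mcd_predict(tm, amb, n_forward = n_forward, seed = seed))
  }
  sd_small <- apply(vapply(1:12, function(s) mean_of(10, s), numeric(12)),
                    1, sd)
  sd_large <- apply(vapply(1:12, function(s) mean_of(200, s), numeric(12)),
                    1, sd)
  # ~ 1/sqrt(n): 20x more passes should cut the spread at least in half
  expect_lt(mean(sd_large), mean(sd_small) / 2)
})

test_that("model pools keep provenance and validate their inputs", {
  m1 <- toy_trained()
  m2 <- toy_trained(ads = TRUE)
  pool <- pool_models(list(m1, m2))
  expect_length(pool, 2)
  expect_equal(attr(pool, "strategy"), "model_pool")

  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(pool, path)
  back <- readRDS(path)
  expect_equal(vapply(back, `[[`, "", "member_id"),
               vapply(pool, `[[`, "", "member_id"))
  expect_equal(predict_proba(back[[1]], te), predict_proba(m1, te))

  expect_error(pool_models(list(m1)), class = "eegensemble_config_error")
  m3 <- m1
  m3$n_channels <- 5L
  expect_error(pool_models(list(m1, m3)), class = "eegensemble_config_error")
})

test_that("band selection equals an exhaustive argmax", {
  set.seed(8)
  for (i in 1:20) {
    scores <- setNames(round(runif(6, 50, 95), 1), eeg_bands()$band)
    top1 <- select_top_bands(scores, 1)
    expect_equal(scores[[top1]], max(scores))
    top3 <- select_top_bands(scores, 3)
    expect_equal(sort(scores[top3], decreasing = TRUE),
                 sort(scores, decreasing = TRUE)[1:3], ignore_attr = TRUE)
  }
  # ties resolve in canonical band order
  tied <- setNames(c(90, 90, 90, 80, 80, 80), eeg_bands()$band)
  expect_equal(select_top_bands(tied, 2), c("delta", "theta"))
})

test_that("the frequency ensemble ranks an alpha-only signal correctly", {
  spec <- cohort_spec(n_subjects = 40, n_channels = 4, sampling_rate = 100,
                      duration = 70,
                      band_effects = list(alpha = c(1, 2)),
                      subject_sd = 0.1, noise_sd = 2,
                      p_flat_channel = 0, p_noisy_channel = 0, seed = 19)
  coh <- generate_cohort(spec)
  labels <- dplyr::bind_rows(lapply(coh, function(r) {
    tibble::tibble(subject_id = r$subject_id, label = r$label)
  }))
  split <- make_folds(labels, 5, seed = 2)
  rot <- rotations(split)[[1]]
  banded <- lapply(coh, decompose_bands)
  names(banded) <- labels$subject_id
  store <- function(ids, role) {
    out <- lapply(eeg_bands()$band, function(b) {
      lapply(ids, function(id) {
        ea <- segment_epochs(banded[[id]][[b]],
                             c(train = 20, validation = 20)[[role]],
                             role, band = b)
        if (role == "train") thin_training_epochs(ea) else ea
      })
    })
    names(out) <- eeg_bands()$band
    out
  }
  btr <- store(rot$train, "train")
  bva <- store(rot$validation, "validation")
  val_labels <- dplyr::filter(labels, subject_id %in% rot$validation)

  ens <- build_frequency_ensemble(
    model_spec("inception", depth = 2, n_filters = 2,
               kernel_sizes = c(7, 15, 31), seed = 3),
    btr, bva, val_labels, top_k = 3,
    training_config(max_iterations = 8, early_stop_patience = 4,
                    lr_patience = 2, lr_init = 0.02, batch_size = 128,
                    seed = 4))
  sel <- attr(ens, "selection")
  expect_equal(nrow(sel), 6)
  expect_equal(sel$band[1], "alpha")
  expect_length(ens, 3)
  expect_equal(ens[[1]]$band, sel$band[1])

  # top_k = 6 keeps every member in validation order (oracle equivalence)
  scores <- setNames(sel$val_subject_accuracy, sel$band)
  expect_equal(select_top_bands(scores[eeg_bands()$band], 6), sel$band)

  bad <- btr[-2]
  expect_error(
    build_frequency_ensemble(toy_spec(), bad, bva, val_labels, 3, quick_cfg),
    regexp = "theta", class = "eegensemble_input_error")
})
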