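#' Configure a full experiment
#'
#' Bundles every stage of the experiment — cohort simulation,
#' preprocessing, cross-validation, ensemble construction, evaluation and
#' uncertainty analysis — into one validated object. The defaults are a
#' compact desk-scale configuration that runs end-to-end on one CPU in
#' minutes. The full-scale reference protocol is expressed with the same
#' arguments: a cohort of 1780 subjects with 129 channels at 500 Hz,
#' `extract = c(train = 120, validation = 60, test = 80)`, depth-4 models
#' with 32 filters per branch, and `training_config()` at its defaults
#' (50 iterations, patience 15/5, initial rate 0.005).
#'
#' @param cohort A [cohort_spec()].
#' @param ensembles Named list of ensemble descriptions; each a list with a
#'   `strategy` in `weights_uniform, weights_normal, depth, ads_mcd,
#'   model_pool, frequency` plus strategy arguments (`n`, `depths`,
#'   `n_forward`, `top_k`).
#' @param base_model A [model_spec()] shared by the ensembles.
#' @param training A [training_config()].
#' @param band_pass Broadband filter edges in Hz.
#' @param extract Named numeric: seconds extracted per role.
#' @param discard_initial_s Seconds discarded from every recording.
#' @param epoch_s Epoch length, seconds.
#' @param schemes Voting schemes to report.
#' @param p_grid Rejection percentages for the uncertainty stage.
#' @param n_folds Cross-validation folds.
#' @param seed Master seed; propagated deterministically to every stage.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              ensembles = list(
                                weights_uniform = list(strategy = "weights_uniform", n = 3L)
                              ),
                              base_model = model_spec("inception", depth = 2L,
                                                      n_filters = 2L),
                              training = training_config(max_iterations = 15L,
                                                         early_stop_patience = 6L,
                                                         lr_patience = 3L),
                              band_pass = c(1, 45),
                              extract = c(train = 40, validation = 20, test = 40),
                              discard_initial_s = 30,
                              epoch_s = 2,
                              schemes = c("ensemble_epoch", "ensemble_subject"),
                              p_grid = c(0, 10, 25, 50, 75, 90),
                              n_folds = 5L,
                              seed = 1L) {
  if (!inherits(cohort, "cohort_spec")) stop_config("cohort must be a cohort_spec")
  known <- c("weights_uniform", "weights_normal", "depth", "ads_mcd",
             "model_pool", "frequency")
  for (nm in names(ensembles)) {
    if (!ensembles[[nm]]$strategy %in% known) {
      stop_config(sprintf("unknown ensemble strategy '%s'",
                          ensembles[[nm]]$strategy))
    }
  }
  if (!all(c("train", "validation", "test") %in% names(extract))) {
    stop_config("extract must name train, validation and test lengths")
  }
  structure(list(
    cohort = cohort, ensembles = ensembles, base_model = base_model,
    training = training, band_pass = band_pass, extract = extract,
    discard_initial_s = discard_initial_s, epoch_s = epoch_s,
    schemes = schemes, p_grid = p_grid, n_folds = as.integer(n_folds),
    seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with top-level keys mirroring the
#'   [experiment_config()] arguments (`cohort`, `ensembles`, `base_model`,
#'   `training`, ...).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_spec, y$cohort)
  args <- list(cohort = cohort)
  if (!is.null(y$base_model)) args$base_model <- do.call(model_spec, y$base_model)
  if (!is.null(y$training)) args$training <- do.call(training_config, y$training)
  if (!is.null(y$ensembles)) args$ensembles <- y$ensembles
  for (nm in c("band_pass", "discard_initial_s", "epoch_s", "schemes",
               "p_grid", "n_folds", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$extract)) args$extract <- unlist(y$extract)
  do.call(experiment_config, args)
}

preprocess_recording <- function(rec, band_pass) {
  report <- qc_channels(rec)
  if (reject_recording(report)) return(NULL)
  rec <- interpolate_channels(rec, report$excluded$channel)
  bandpass(rec, band_pass[1], band_pass[2])
}

role_epochs <- function(rec, role, config, band = "broadband") {
  ea <- segment_epochs(rec, config$extract[[role]], role,
                       epoch_s = config$epoch_s,
                       discard_initial_s = config$discard_initial_s,
                       band = band)
  if (role == "train") ea <- thin_training_epochs(ea)
  ea
}

build_configured_ensemble <- function(name, desc, base, stores, val_labels,
                                      cfg) {
  switch(desc$strategy,
    weights_uniform = build_weight_ensemble(base, "uniform", desc$n %||% 5L,
                                            stores$train, stores$validation, cfg),
    weights_normal = build_weight_ensemble(base, "normal", desc$n %||% 5L,
                                           stores$train, stores$validation, cfg),
    depth = build_depth_ensemble(base, desc$depths %||% c(2L, 4L, 6L, 8L, 10L),
                                 stores$train, stores$validation, cfg),
    ads_mcd = {
      spec_i <- base
      spec_i$ads <- TRUE
      m <- train_member(spec_i, stores$train, stores$validation, cfg, "ads")
      ens <- new_ensemble(list(m), "ads_mcd")
      attr(ens, "n_forward") <- desc$n_forward %||% 50L
      ens
    },
    frequency = build_frequency_ensemble(base, stores$banded_train,
                                         stores$banded_validation, val_labels,
                                         desc$top_k %||% 3L, cfg),
    model_pool = {
      specs <- list(base,
                    utils::modifyList(base, list(family = "eegnet")),
                    utils::modifyList(base, list(ads = TRUE)))
      members <- lapply(seq_along(specs), function(i) {
        s <- specs[[i]]
        class(s) <- "eeg_model_spec"
        s$seed <- derive_seed(base$seed, 400L + i)
        train_member(s, stores$train, stores$validation, cfg,
                     sprintf("pool_%d", i))
      })
      pool_models(members)
    },
    stop_config(sprintf("unknown ensemble strategy '%s'", desc$strategy))
  )
}

#' Run a full experiment
#'
#' Simulates the cohort, applies the cleaning rules (channel QC, recording
#' rejection, interpolation, broadband filtering), builds the stratified
#' folds, and for every rotation trains each configured ensemble, predicts
#' the test fold, evaluates every voting scheme and computes the rejection
#' curve. All outputs are written as plain CSV/JSON under `out_dir` and
#' returned invisibly; the whole run is a deterministic function of the
#' configuration.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with tibbles `evaluation`, `rejection`,
#'   `cv_summary` and the run manifest.
#' @export
run_experiment <- function(config, out_dir) {
  if (!inherits(config, "experiment_config")) {
    stop_config("config must be an experiment_config")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  needs_bands <- any(vapply(config$ensembles,
                            function(d) d$strategy == "frequency", TRUE))

  cohort <- generate_cohort(config$cohort)
  kept <- list()
  for (rec in cohort) {
    pp <- preprocess_recording(rec, config$band_pass)
    if (!is.null(pp)) kept[[length(kept) + 1L]] <- pp
  }
  if (length(kept) < 2L * config$n_folds) {
    stop_input("too few recordings survived quality control")
  }
  subjects <- dplyr::bind_rows(lapply(kept, function(r) {
    tibble(subject_id = r$subject_id, label = r$label)
  }))
  names(kept) <- subjects$subject_id
  split <- make_folds(subjects, config$n_folds, seed = config$seed)
  rots <- rotations(split)

  banded <- NULL
  if (needs_bands) {
    banded <- lapply(kept, decompose_bands)
  }

  eval_rows <- list()
  rej_rows <- list()
  for (r in seq_along(rots)) {
    rot <- rots[[r]]
    stopifnot(length(intersect(rot$train, rot$test)) == 0,
              length(intersect(rot$train, rot$validation)) == 0,
              length(intersect(rot$validation, rot$test)) == 0)
    make_store <- function(ids, role) {
      lapply(kept[ids], role_epochs, role = role, config = config)
    }
    stores <- list(
      train = make_store(rot$train, "train"),
      validation = make_store(rot$validation, "validation"),
      test = make_store(rot$test, "test")
    )
    if (needs_bands) {
      banded_store <- function(ids, role) {
        out <- lapply(band_names(), function(b) {
          lapply(ids, function(id) {
            role_epochs(banded[[id]][[b]], role, config, band = b)
          })
        })
        names(out) <- band_names()
        out
      }
      stores$banded_train <- banded_store(rot$train, "train")
      stores$banded_validation <- banded_store(rot$validation, "validation")
      stores$banded_test <- banded_store(rot$test, "test")
    }
    val_labels <- dplyr::filter(subjects, .data$subject_id %in% rot$validation)
    test_labels <- dplyr::filter(subjects, .data$subject_id %in% rot$test)

    for (nm in names(config$ensembles)) {
      desc <- config$ensembles[[nm]]
      base <- config$base_model
      base$seed <- derive_seed(config$seed, 1000L * r + match(nm, names(config$ensembles)))
      ens <- tryCatch(
        build_configured_ensemble(nm, desc, base, stores, val_labels,
                                  config$training),
        error = function(e) {
          abort(sprintf("stage 'ensemble %s', rotation %d failed: %s",
                        nm, r, conditionMessage(e)),
                class = "eegensemble_error", parent = e)
        }
      )
      tensor <- if (identical(attr(ens, "strategy"), "ads_mcd")) {
        mcd_predict(ens[[1]], stores$test,
                    n_forward = attr(ens, "n_forward"),
                    seed = derive_seed(config$seed, 2000L + r))
      } else {
        ensemble_predict(ens, stores$test,
                         banded_epochs = stores$banded_test)
      }
      for (scheme in config$schemes) {
        ev <- evaluate_tensor(tensor, test_labels, scheme)
        ev$fold <- r
        ev$ensemble <- nm
        eval_rows[[length(eval_rows) + 1L]] <- ev
        rc <- rejection_curve(tensor, test_labels, scheme, config$p_grid)
        rc$fold <- r
        rc$ensemble <- nm
        rc$scheme <- scheme
        rej_rows[[length(rej_rows) + 1L]] <- as_tibble(rc)
      }
    }
  }

  evaluation <- dplyr::bind_rows(eval_rows)
  rejection <- dplyr::bind_rows(rej_rows)
  cv_summary <- summarize_cv(dplyr::select(
    evaluation, dplyr::all_of(c("fold", "scheme", "ensemble",
                                "per_epoch_accuracy", "per_subject_accuracy",
                                "auc"))))
  manifest <- list(
    seed = config$seed,
    n_subjects = config$cohort$n_subjects,
    n_recordings_kept = length(kept),
    n_folds = config$n_folds,
    ensembles = names(config$ensembles),
    schemes = config$schemes,
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(rejection, file.path(out_dir, "rejection_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(cv_summary, file.path(out_dir, "cv_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(evaluation = evaluation, rejection = rejection,
                 cv_summary = cv_summary, manifest = manifest))
}

#' Band-restricted cross-validated classification
#'
#' The frequency-explainability analysis: for each requested band, every
#' recording is filtered to that band (after the standard cleaning rules:
#' channel QC, rejection, interpolation, broadband filtering), a classifier
#' is trained per cross-validation rotation on the band-limited epochs, and
#' test-fold performance is recorded. `"broadband"` may be included to
#' benchmark the unfiltered signal.
#'
#' @param recordings List of `eeg_recording`s (a generated or read cohort).
#' @param bands Character vector of canonical band names and/or
#'   `"broadband"`.
#' @param base_model A [model_spec()].
#' @param training A [training_config()].
#' @param extract Named numeric: seconds extracted per role.
#' @param discard_initial_s,epoch_s Segmentation parameters.
#' @param band_pass Broadband cleaning filter edges.
#' @param n_folds,seed Cross-validation setup.
#' @return A tibble `band, fold, per_epoch_accuracy, per_subject_accuracy,
#'   auc, n_subjects, n_epochs`.
#' @export
band_cv <- function(recordings, bands, base_model, training,
                    extract = c(train = 20, validation = 20, test = 40),
                    discard_initial_s = 30, epoch_s = 2,
                    band_pass = c(1, 45), n_folds = 5L, seed = 1L) {
  stopifnot(all(bands %in% c(band_names(), "broadband")))
  kept <- list()
  for (rec in recordings) {
    pp <- preprocess_recording(rec, band_pass)
    if (!is.null(pp)) kept[[pp$subject_id]] <- pp
  }
  subjects <- dplyr::bind_rows(lapply(kept, function(r) {
    tibble(subject_id = r$subject_id, label = r$label)
  }))
  split <- make_folds(subjects, n_folds, seed = seed)
  rots <- rotations(split)
  rows <- list()
  for (band in bands) {
    banded <- if (band == "broadband") {
      kept
    } else {
      edges <- band_edges(band)
      lapply(kept, bandpass, low = edges[["low"]], high = edges[["high"]])
    }
    for (r in seq_along(rots)) {
      rot <- rots[[r]]
      mk <- function(ids, role) {
        lapply(banded[ids], function(rc) {
          ea <- segment_epochs(rc, extract[[role]], role, epoch_s = epoch_s,
                               discard_initial_s = discard_initial_s,
                               band = band)
          if (role == "train") thin_training_epochs(ea) else ea
        })
      }
      spec_i <- base_model
      spec_i$seed <- derive_seed(seed, 3000L + 100L * match(band, bands) + r)
      trained <- train_member(spec_i, mk(rot$train, "train"),
                              mk(rot$validation, "validation"), training,
                              sprintf("%s_fold%d", band, r), band = band)
      te_ds <- as_eeg_dataset(mk(rot$test, "test"))
      tensor <- prediction_tensor(matrix(predict_proba(trained, te_ds), 1),
                                  te_ds$subject)
      ev <- evaluate_tensor(tensor, subjects, "ensemble_epoch")
      ev$band <- band
      ev$fold <- r
      ev$scheme <- NULL
      rows[[length(rows) + 1L]] <- ev
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("band", "fold", "per_epoch_accuracy",
                                  "per_subject_accuracy", "auc", "n_subjects",
                                  "n_epochs")))
}

#' Per-band performance report
#'
#' Aggregates per-band, per-run, per-fold accuracies into the three
#' figures reported for the frequency analysis: the best single-fold
#' accuracy, the best run mean (mean over folds within a run, maximized
#' over runs), and the overall mean across all runs and folds. For every
#' band, best single fold >= best run mean >= overall mean.
#'
#' @param accuracies A data frame `band, run, fold, accuracy`.
#' @return A tibble `band, best_fold, best_run_mean, overall_mean` of class
#'   `band_report`.
#' @export
band_report <- function(accuracies) {
  accuracies <- as_tibble(accuracies)
  need <- c("band", "run", "fold", "accuracy")
  if (!all(need %in% names(accuracies))) {
    stop_input(sprintf("accuracies must have columns %s",
                       paste(need, collapse = ", ")))
  }
  missing_bands <- setdiff(unique(accuracies$band), band_names())
  if (length(missing_bands) > 0) {
    stop_input(sprintf("unknown band(s): %s",
                       paste(missing_bands, collapse = ", ")))
  }
  out <- accuracies |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(
      best_fold = max(.data$accuracy),
      best_run_mean = max(tapply(.data$accuracy, .data$run, mean)),
      overall_mean = mean(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$band, band_names()))
  class(out) <- c("band_report", class(out))
  out
}
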