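#' Construct a prediction tensor
#'
#' A members x epochs matrix of class-1 probabilities with the owning
#' subject of each epoch attached; the common currency between ensembles,
#' voting and the uncertainty procedure (Monte Carlo dropout forward passes
#' use the same shape, with passes as rows).
#'
#' @param probs Numeric matrix `[n_members x n_epochs]`, entries in `[0,1]`.
#' @param epoch_subject Character vector of the subject owning each epoch.
#' @param member_ids Optional member labels.
#' @return A `prediction_tensor`.
#' @export
prediction_tensor <- function(probs, epoch_subject, member_ids = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(epoch_subject)) {
    stop_input("epoch_subject must have one entry per tensor column")
  }
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_input("tensor entries must be probabilities in [0, 1]")
  }
  member_ids <- member_ids %||% sprintf("member_%02d", seq_len(nrow(probs)))
  structure(probs,
            epoch_subject = as.character(epoch_subject),
            member_ids = member_ids,
            class = c("prediction_tensor", "matrix", "array"))
}

#' @export
print.prediction_tensor <- function(x, ...) {
  cat(sprintf("<prediction_tensor> %d members x %d epochs (%d subjects)\n",
              nrow(x), ncol(x), length(unique(attr(x, "epoch_subject")))))
  invisible(x)
}

#' @rdname prediction_tensor
#' @param x A `prediction_tensor`.
#' @param ... Unused.
#' @export
tidy.prediction_tensor <- function(x, ...) {
  tibble(
    member = rep(attr(x, "member_ids"), times = ncol(x)),
    epoch = rep(seq_len(ncol(x)), each = nrow(x)),
    subject_id = rep(attr(x, "epoch_subject"), each = nrow(x)),
    prob = as.numeric(x)
  )
}

train_member <- function(spec, train_epochs, val_epochs, cfg, member_id,
                         band = NULL) {
  ds <- as_eeg_dataset(train_epochs)
  model <- build_model(spec, dim(ds$x)[1], dim(ds$x)[2])
  trained <- tryCatch(
    train_model(model, ds, val_epochs, cfg),
    error = function(e) {
      abort(sprintf("training of ensemble member '%s' failed: %s",
                    member_id, conditionMessage(e)),
            class = "eegensemble_error", parent = e)
    }
  )
  trained$member_id <- member_id
  if (!is.null(band)) trained$band <- band
  trained
}

#' Weight-randomization ensemble
#'
#' Trains `n` copies of the same architecture whose only difference is the
#' kernel initializer draw: each member uses the requested distribution
#' (`uniform` in \[-0.05, 0.05\] or `normal` with sd 0.05) under a
#' different seed, then trains independently on the same data.
#'
#' @param base A [model_spec()] (its `init_scheme` is overridden).
#' @param dist `"uniform"` or `"normal"`.
#' @param n Number of members (>= 2).
#' @param train_epochs,val_epochs Epoch data.
#' @param cfg A [training_config()].
#' @return A list of `eeg_trained_model`s of class `eeg_ensemble` with
#'   strategy metadata.
#' @export
build_weight_ensemble <- function(base, dist = c("uniform", "normal"), n = 5L,
                                  train_epochs, val_epochs,
                                  cfg = training_config()) {
  dist <- match.arg(dist)
  if (!is_count(n) || n < 2) stop_config("a weight ensemble needs n >= 2 members")
  scheme <- paste0("random_", dist)
  members <- lapply(seq_len(n), function(i) {
    spec_i <- base
    spec_i$init_scheme <- scheme
    spec_i$seed <- derive_seed(base$seed, 100L + i)
    train_member(spec_i, train_epochs, val_epochs, cfg,
                 sprintf("weights_%s_%d", dist, i))
  })
  new_ensemble(members, paste0("weights_", dist))
}

#' Depth ensemble
#'
#' One member per inception depth in `depths` (default 2, 4, 6, 8, 10), in
#' the given order; member metadata records the depth.
#'
#' @param base A [model_spec()] of the inception family.
#' @param depths Depths, all in \{2, 4, 6, 8, 10\}.
#' @inheritParams build_weight_ensemble
#' @return An `eeg_ensemble`.
#' @export
build_depth_ensemble <- function(base, depths = c(2L, 4L, 6L, 8L, 10L),
                                 train_epochs, val_epochs,
                                 cfg = training_config()) {
  if (length(depths) == 0) stop_config("depths must be non-empty")
  if (!all(depths %in% c(2L, 4L, 6L, 8L, 10L))) {
    stop_config("depths must lie in {2, 4, 6, 8, 10}")
  }
  members <- lapply(seq_along(depths), function(i) {
    spec_i <- base
    spec_i$depth <- as.integer(depths[i])
    spec_i$seed <- derive_seed(base$seed, 200L + i)
    m <- train_member(spec_i, train_epochs, val_epochs, cfg,
                      sprintf("depth_%d", depths[i]))
    m$depth <- as.integer(depths[i])
    m
  })
  new_ensemble(members, "depth")
}

#' Monte Carlo dropout prediction
#'
#' Runs `n_forward` stochastic forward passes with the dropout layers
#' active at prediction time; each pass is one row of the returned tensor,
#' so downstream voting and variance code treat the passes exactly like
#' ensemble members. The ensemble point prediction is the per-epoch mean
#' over passes.
#'
#' @param trained An `eeg_trained_model` whose network contains a dropout
#'   layer (e.g. built with `ads = TRUE`).
#' @param epochs Epoch data.
#' @param n_forward Number of forward passes (>= 2).
#' @param seed Seed for the dropout masks; the tensor is reproducible.
#' @return A `prediction_tensor` of `[n_forward x n_epochs]`.
#' @export
mcd_predict <- function(trained, epochs, n_forward = 50L, seed = 1L) {
  if (!isTRUE(trained$net$has_dropout)) {
    stop_config("Monte Carlo dropout requires a model with a dropout layer")
  }
  if (!is_count(n_forward) || n_forward < 2) {
    stop_config("n_forward must be an integer >= 2")
  }
  ds <- as_eeg_dataset(epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 31L))
  xs <- ds$x / (trained$x_scale %||% 1)
  probs <- matrix(0, n_forward, length(ds$y))
  for (i in seq_len(n_forward)) {
    probs[i, ] <- stats::plogis(net_predict_logits(trained$net, xs,
                                                   stoch = TRUE))
  }
  prediction_tensor(probs, ds$subject,
                    sprintf("forward_pass_%02d", seq_len(n_forward)))
}

#' Frequency ensemble
#'
#' Trains one member per canonical band on band-filtered epochs, ranks the
#' six members by validation per-subject majority-vote accuracy, and keeps
#' the `top_k` best. At prediction time each member receives the test
#' epochs filtered to its own band by default (`ensemble_predict()` with
#' `banded_epochs`); a broadband evaluation is available by passing the
#' unfiltered epochs to every member.
#'
#' @param base A [model_spec()].
#' @param banded_train,banded_val Named lists (one entry per canonical
#'   band) of epoch data filtered to that band.
#' @param val_labels Data frame `subject_id, label` for the validation
#'   subjects.
#' @param top_k Members kept after ranking.
#' @inheritParams build_weight_ensemble
#' @return An `eeg_ensemble` with a `selection` tibble of all six
#'   validation scores attached.
#' @export
build_frequency_ensemble <- function(base, banded_train, banded_val,
                                     val_labels, top_k = 3L,
                                     cfg = training_config()) {
  missing_tr <- setdiff(band_names(), names(banded_train))
  if (length(missing_tr) > 0) {
    stop_input(sprintf("missing banded training store for: %s",
                       paste(missing_tr, collapse = ", ")))
  }
  missing_va <- setdiff(band_names(), names(banded_val))
  if (length(missing_va) > 0) {
    stop_input(sprintf("missing banded validation store for: %s",
                       paste(missing_va, collapse = ", ")))
  }
  members <- lapply(seq_along(band_names()), function(i) {
    band <- band_names()[i]
    spec_i <- base
    spec_i$seed <- derive_seed(base$seed, 300L + i)
    train_member(spec_i, banded_train[[band]], banded_val[[band]], cfg,
                 sprintf("band_%s", band), band = band)
  })
  names(members) <- band_names()
  scores <- vapply(members, function(m) {
    val_ds <- as_eeg_dataset(banded_val[[m$band]])
    tensor <- prediction_tensor(matrix(predict_proba(m, val_ds), 1),
                                val_ds$subject)
    evaluate_tensor(tensor, val_labels, "ensemble_epoch")$per_subject_accuracy
  }, 0)
  selection <- tibble(
    band = band_names(),
    val_subject_accuracy = as.numeric(scores)
  ) |> dplyr::arrange(dplyr::desc(.data$val_subject_accuracy))
  keep <- select_top_bands(setNames(scores, band_names()), top_k)
  ens <- new_ensemble(unname(members[keep]), "frequency")
  attr(ens, "selection") <- selection
  ens
}

#' Select the best bands by validation score
#'
#' Picks the `k` highest-scoring bands, ties broken by canonical band
#' order. Exposed separately so the selection is directly comparable with
#' an exhaustive argmax.
#'
#' @param scores Named numeric of per-band validation scores.
#' @param k Number of bands to keep.
#' @return Character vector of band names, best first.
#' @export
select_top_bands <- function(scores, k) {
  ord <- order(-scores, match(names(scores), band_names()))
  names(scores)[ord][seq_len(min(k, length(scores)))]
}

#' Pool previously trained models into a heterogeneous ensemble
#'
#' Combines members from earlier strategies (plain and ADS variants of
#' both families, depth variations, ...) into one ensemble; provenance
#' metadata (`member_id`, family, depth, band) is preserved.
#'
#' @param members A list of `eeg_trained_model`s (>= 2) with identical
#'   input dimensions.
#' @return An `eeg_ensemble` with strategy `"model_pool"`.
#' @export
pool_models <- function(members) {
  if (length(members) < 2) {
    stop_config("a model pool needs at least 2 members")
  }
  dims <- t(vapply(members, function(m) c(m$n_channels, m$samples_per_epoch),
                   c(0L, 0L)))
  if (nrow(unique(dims)) != 1) {
    stop_config("pooled members disagree on input dimensions")
  }
  members <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    m$member_id <- m$member_id %||% sprintf("pool_member_%02d", i)
    m
  })
  new_ensemble(members, "model_pool")
}

new_ensemble <- function(members, strategy) {
  structure(members, strategy = strategy, class = "eeg_ensemble")
}

#' @export
print.eeg_ensemble <- function(x, ...) {
  cat(sprintf("<eeg_ensemble> strategy %s | %d members\n",
              attr(x, "strategy"), length(x)))
  invisible(x)
}

#' Predict with an ensemble
#'
#' Row `i` of the result is member `i`'s deterministic [predict_proba()]
#' over all epochs. Members carrying a band tag receive their band-filtered
#' epochs from `banded_epochs` (the frequency-ensemble default); with
#' `broadband_input = TRUE` every member sees the unfiltered epochs.
#'
#' @param members An `eeg_ensemble` or list of `eeg_trained_model`s.
#' @param epochs Broadband epoch data.
#' @param banded_epochs Optional named list of band-filtered epoch data.
#' @param broadband_input Force broadband input for banded members.
#' @return A `prediction_tensor` `[n_members x n_epochs]`.
#' @export
ensemble_predict <- function(members, epochs, banded_epochs = NULL,
                             broadband_input = FALSE) {
  if (length(members) == 0) stop_input("no ensemble members")
  ds <- as_eeg_dataset(epochs)
  rows <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    input <- ds
    if (!broadband_input && !is.null(m$band) && m$band != "broadband") {
      if (is.null(banded_epochs[[m$band]])) {
        stop_input(sprintf("no banded epochs supplied for member band '%s'",
                           m$band))
      }
      input <- as_eeg_dataset(banded_epochs[[m$band]])
    }
    tryCatch(
      predict_proba(m, input),
      error = function(e) {
        abort(sprintf("prediction failed for ensemble member '%s': %s",
                      m$member_id %||% as.character(i), conditionMessage(e)),
              class = "eegensemble_error", parent = e)
      }
    )
  })
  prediction_tensor(
    do.call(rbind, rows), ds$subject,
    vapply(seq_along(members), function(i) {
      members[[i]]$member_id %||% sprintf("member_%02d", i)
    }, "")
  )
}
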