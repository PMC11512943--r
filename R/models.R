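#' Specify a compact EEG classifier
#'
#' Describes one of the two supported convolutional families:
#'
#' * `"inception"` — a stack of `depth` inception modules (parallel temporal
#'   convolutions of several kernel lengths plus a max-pool branch, merged
#'   and rectified), with a shortcut connection added every third module,
#'   global average pooling over time, and a sigmoid output unit.
#' * `"eegnet"` — a temporal filter bank shared across channels, a depthwise
#'   spatial filter over channels, then a separable temporal convolution,
#'   with average pooling and dropout between blocks.
#'
#' Widths default to a compact, CPU-friendly scale; the published full-size
#' widths can be requested through `n_filters` and the `eegnet` list.
#' `ads = TRUE` appends the adapted dropout head — a 32-unit dense layer
#' followed by dropout — which enables Monte Carlo dropout at prediction
#' time (see [mcd_predict()]).
#'
#' @param family `"inception"` or `"eegnet"`.
#' @param depth Number of inception modules; one of 2, 4, 6, 8, 10
#'   (ignored by the eegnet family).
#' @param ads Append the 32-unit dense + dropout head.
#' @param dropout_rate Dropout probability of the adapted head.
#' @param init_scheme `"glorot_uniform"` (default), `"random_uniform"` or
#'   `"random_normal"`.
#' @param seed Integer seed controlling weight initialization.
#' @param n_filters Filters per inception branch.
#' @param bottleneck Width of the inception bottleneck (defaults to
#'   `n_filters`).
#' @param kernel_sizes Temporal kernel lengths of the parallel inception
#'   convolutions.
#' @param eegnet Named list of eegnet widths: `f1` temporal filters,
#'   `d` spatial filters per temporal filter, `f2` pointwise filters,
#'   `temporal_kernel`, `separable_kernel`, `pool1`, `pool2`,
#'   `block_dropout`.
#' @return An object of class `eeg_model_spec`.
#' @export
model_spec <- function(family = c("inception", "eegnet"),
                       depth = 4L,
                       ads = FALSE,
                       dropout_rate = 0.5,
                       init_scheme = c("glorot_uniform", "random_uniform",
                                       "random_normal"),
                       seed = 1L,
                       n_filters = 8L,
                       bottleneck = NULL,
                       kernel_sizes = c(9L, 19L, 39L),
                       eegnet = list()) {
  family <- match.arg(family)
  init_scheme <- match.arg(init_scheme)
  if (family == "inception" && !depth %in% c(2L, 4L, 6L, 8L, 10L)) {
    stop_config("inception depth must be one of 2, 4, 6, 8, 10")
  }
  if (isTRUE(ads) && (dropout_rate <= 0 || dropout_rate >= 1)) {
    stop_config("the adapted dropout head requires dropout_rate in (0, 1)")
  }
  if (any(kernel_sizes %% 2 == 0)) {
    stop_config("kernel_sizes must be odd so same-padding is centre-aligned")
  }
  en <- utils::modifyList(list(
    f1 = 4L, d = 2L, f2 = 8L, temporal_kernel = 33L, separable_kernel = 9L,
    pool1 = 4L, pool2 = 8L, block_dropout = 0.25
  ), eegnet)
  structure(list(
    family = family, depth = as.integer(depth), ads = isTRUE(ads),
    dropout_rate = dropout_rate, init_scheme = init_scheme,
    seed = as.integer(seed), n_filters = as.integer(n_filters),
    bottleneck = as.integer(bottleneck %||% n_filters),
    kernel_sizes = as.integer(kernel_sizes), eegnet = en
  ), class = "eeg_model_spec")
}

#' Training protocol configuration
#'
#' Defaults are the full-scale reference protocol: up to 50 iterations (full passes over
#' the training epochs), early stopping with a patience of 15 iterations on
#' the validation loss, a learning-rate scheduler that halves the rate after
#' 5 non-improving iterations, an initial rate of 0.005, and retention of
#' the checkpoint with the lowest validation loss.
#'
#' @param max_iterations Maximum training iterations.
#' @param early_stop_patience Consecutive non-improving iterations after
#'   which training halts.
#' @param lr_init Initial Adam learning rate.
#' @param lr_patience Non-improving iterations before the rate is decayed.
#' @param lr_factor Multiplicative learning-rate decay.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling minibatch order and dropout.
#' @return An object of class `eeg_training_config`.
#' @export
training_config <- function(max_iterations = 50L,
                            early_stop_patience = 15L,
                            lr_init = 0.005,
                            lr_patience = 5L,
                            lr_factor = 0.5,
                            batch_size = 64L,
                            seed = 1L) {
  if (!is_count(max_iterations)) stop_config("max_iterations must be a positive integer")
  if (lr_init <= 0) stop_config("lr_init must be positive")
  structure(list(
    max_iterations = as.integer(max_iterations),
    early_stop_patience = as.integer(early_stop_patience),
    lr_init = lr_init,
    lr_patience = as.integer(lr_patience),
    lr_factor = lr_factor,
    batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "eeg_training_config")
}

#' Build an untrained classifier
#'
#' Instantiates the network described by a [model_spec()] for a given input
#' geometry. Weights are drawn from the spec's initializer under the spec's
#' seed, so two builds from the same spec are bit-identical.
#'
#' @param spec An [model_spec()].
#' @param n_channels,samples_per_epoch Input dimensions of one epoch.
#' @return An object of class `eeg_model`.
#' @export
build_model <- function(spec, n_channels, samples_per_epoch) {
  if (!inherits(spec, "eeg_model_spec")) stop_config("spec must be an eeg_model_spec")
  if (!is_count(n_channels) || !is_count(samples_per_epoch)) {
    stop_config("input dimensions must be positive integers")
  }
  init <- weight_init_fun(spec$init_scheme)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  net <- if (spec$family == "inception") {
    build_inception_net(n_channels, samples_per_epoch, spec$depth,
                        spec$n_filters, spec$bottleneck, spec$kernel_sizes,
                        spec$ads, spec$dropout_rate, init)
  } else {
    en <- spec$eegnet
    build_eegnet_net(n_channels, samples_per_epoch, en$f1, en$d, en$f2,
                     en$temporal_kernel, en$separable_kernel, en$pool1,
                     en$pool2, en$block_dropout, spec$ads, spec$dropout_rate,
                     init)
  }
  structure(list(
    spec = spec, net = net,
    n_channels = as.integer(n_channels),
    samples_per_epoch = as.integer(samples_per_epoch),
    n_params = net_n_params(net)
  ), class = "eeg_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model> %s%s | input %d ch x %d samples | %d parameters\n",
              x$spec$family,
              if (x$spec$family == "inception") paste0(" depth ", x$spec$depth) else "",
              x$n_channels, x$samples_per_epoch, x$n_params))
  invisible(x)
}

# early-stopping / learning-rate controller ----------------------------------
# Pure state machine so the patience arithmetic is testable on scripted loss
# sequences: improvement = strictly lower validation loss than the best seen.

controller_new <- function(early_stop_patience, lr_patience, lr_factor, lr_init) {
  list(best = Inf, best_iteration = 0L, iteration = 0L,
       since_improve = 0L, lr_since = 0L,
       lr = lr_init,
       early_stop_patience = early_stop_patience,
       lr_patience = lr_patience, lr_factor = lr_factor)
}

controller_step <- function(ctrl, val_loss) {
  ctrl$iteration <- ctrl$iteration + 1L
  improved <- val_loss < ctrl$best
  if (improved) {
    ctrl$best <- val_loss
    ctrl$best_iteration <- ctrl$iteration
    ctrl$since_improve <- 0L
    ctrl$lr_since <- 0L
  } else {
    ctrl$since_improve <- ctrl$since_improve + 1L
    ctrl$lr_since <- ctrl$lr_since + 1L
    if (ctrl$lr_since >= ctrl$lr_patience) {
      ctrl$lr <- ctrl$lr * ctrl$lr_factor
      ctrl$lr_since <- 0L
    }
  }
  ctrl$improved <- improved
  ctrl$stop <- ctrl$since_improve >= ctrl$early_stop_patience
  ctrl
}

# training --------------------------------------------------------------------

net_predict_logits <- function(net, x, batch_size = 512L, stoch = FALSE) {
  n <- dim(x)[3]
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx] <- net$fw(x[, , idx, drop = FALSE], stoch = stoch)
  }
  out
}

#' Train a classifier with early stopping and checkpointing
#'
#' Runs minibatch Adam on binary cross-entropy for at most
#' `config$max_iterations` passes over the training epochs. After every
#' iteration the validation loss is evaluated; training halts early when it
#' has not improved for `early_stop_patience` consecutive iterations, the
#' learning rate is decayed by `lr_factor` after `lr_patience` non-improving
#' iterations, and the parameters achieving the lowest validation loss are
#' the ones returned.
#'
#' @param model An untrained [build_model()] result (left unmodified; the
#'   network is copied).
#' @param train_epochs,val_epochs Epoch data: an `epoch_array`, a list of
#'   them, or an `eeg_dataset`.
#' @param config A [training_config()].
#' @return An object of class `eeg_trained_model` with the best checkpoint,
#'   `best_val_loss`, `best_iteration` and a per-iteration `history` tibble.
#' @export
train_model <- function(model, train_epochs, val_epochs,
                        config = training_config()) {
  if (!inherits(model, "eeg_model")) stop_config("model must be an eeg_model")
  train <- as_eeg_dataset(train_epochs)
  val <- as_eeg_dataset(val_epochs)
  if (length(train$y) == 0 || length(val$y) == 0) {
    stop_input("training and validation sets must be non-empty")
  }
  if (!all(dim(train$x)[1:2] == c(model$n_channels, model$samples_per_epoch))) {
    stop_input("training epochs do not match the model's input dimensions")
  }
  if (length(unique(train$y)) < 2) {
    stop_input("training labels contain a single class; both classes are required")
  }

  # fresh copy of the model so the input object stays untrained
  model2 <- build_model(model$spec, model$n_channels, model$samples_per_epoch)
  net <- model2$net

  # global input scaling: one constant for the whole training set, so the
  # network sees unit-order activations while between-epoch amplitude
  # differences (the class signal) are preserved
  x_scale <- stats::sd(train$x)
  if (!is.finite(x_scale) || x_scale == 0) x_scale <- 1
  train$x <- train$x / x_scale
  val <- list(x = val$x / x_scale, y = val$y)
  opt <- adam_new(net)
  ctrl <- controller_new(config$early_stop_patience, config$lr_patience,
                         config$lr_factor, config$lr_init)
  best_params <- net_params(net)
  history <- vector("list", config$max_iterations)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 7L))
  n <- length(train$y)
  for (iter in seq_len(config$max_iterations)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tloss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- train$x[, , idx, drop = FALSE]
      yb <- train$y[idx]
      logits <- net$fw(xb, stoch = TRUE)
      p <- stats::plogis(logits)
      tloss <- tloss + bce_loss(p, yb) * length(idx)
      net$bw((p - yb) / length(idx))
      opt <- adam_step(net, opt, ctrl$lr)
    }
    val_loss <- bce_loss(stats::plogis(net_predict_logits(net, val$x)), val$y)
    ctrl <- controller_step(ctrl, val_loss)
    history[[iter]] <- tibble(
      iteration = iter, train_loss = tloss / n, val_loss = val_loss,
      lr = ctrl$lr
    )
    if (ctrl$improved) best_params <- net_params(net)
    if (ctrl$stop) break
  }
  net_set_params(net, best_params)

  structure(list(
    spec = model$spec,
    net = net,
    n_channels = model$n_channels,
    samples_per_epoch = model$samples_per_epoch,
    n_params = model2$n_params,
    x_scale = x_scale,
    best_val_loss = ctrl$best,
    best_iteration = ctrl$best_iteration,
    history = dplyr::bind_rows(history),
    band = attr(train, "band") %||% train$band %||% "broadband"
  ), class = "eeg_trained_model")
}

#' @export
print.eeg_trained_model <- function(x, ...) {
  cat(sprintf(
    "<eeg_trained_model> %s | band %s | %d params | best val loss %.4f (iteration %d/%d)\n",
    x$spec$family, x$band, x$n_params, x$best_val_loss, x$best_iteration,
    nrow(x$history)))
  invisible(x)
}

#' Predict class-1 probabilities per epoch
#'
#' Deterministic forward pass (dropout disabled) returning one probability
#' of class 1 per epoch.
#'
#' @param trained An `eeg_trained_model`.
#' @param epochs Epoch data (`epoch_array`, list of them, or `eeg_dataset`).
#' @param batch_size Forward-pass batch size.
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(trained, epochs, batch_size = 512L) {
  ds <- as_eeg_dataset(epochs)
  if (!all(dim(ds$x)[1:2] == c(trained$n_channels, trained$samples_per_epoch))) {
    stop_input(sprintf(
      "epoch dimensions [%d ch x %d samples] do not match the model [%d x %d]",
      dim(ds$x)[1], dim(ds$x)[2], trained$n_channels, trained$samples_per_epoch))
  }
  stats::plogis(net_predict_logits(trained$net, ds$x / (trained$x_scale %||% 1),
                                   batch_size))
}

#' @rdname tidy.eeg_trained_model
#' @export
tidy.eeg_trained_model <- function(x, ...) {
  x$history
}

#' Tidy and one-row summaries of a trained classifier
#'
#' `tidy()` returns the per-iteration training history; `glance()` returns a
#' one-row summary.
#'
#' @param x An `eeg_trained_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.eeg_trained_model <- function(x, ...) {
  tibble(
    family = x$spec$family, band = x$band, n_params = x$n_params,
    iterations = nrow(x$history), best_iteration = x$best_iteration,
    best_val_loss = x$best_val_loss
  )
}
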