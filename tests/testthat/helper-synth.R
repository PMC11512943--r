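# shared fixtures, all generated in code

# a recording built directly from a data matrix (µV)
raw_recording <- function(data, fs = 100, label = 0L, id = "T0001") {
  structure(list(
    subject_id = id, label = as.integer(label), data = data,
    sampling_rate = fs,
    channel_positions = eegensemble:::fibonacci_sphere(nrow(data))
  ), class = "eeg_recording")
}

# linearly separable toy task: constant-channel epochs from two Gaussian
# blobs, rendered as epoch_arrays (one subject per class and role)
toy_epochs <- function(n_per_class, role = "train", n_channels = 4,
                       spe = 50, seed = 1) {
  set.seed(seed)
  lapply(0:1, function(cls) {
    mu <- if (cls == 1) 1 else -1
    data <- array(0, c(n_per_class, n_channels, spe))
    for (i in seq_len(n_per_class)) {
      data[i, , ] <- matrix(rnorm(n_channels, mu, 0.5), n_channels, spe)
    }
    structure(list(
      data = data, subject_id = sprintf("%s_%d", role, cls),
      label = cls, epoch_onsets = 2 * (seq_len(n_per_class) - 1),
      role = role, band = "broadband", sampling_rate = spe / 2
    ), class = "epoch_array")
  })
}

toy_spec <- function(...) {
  model_spec("inception", depth = 2L, n_filters = 2L,
             kernel_sizes = c(3L, 7L, 11L), ...)
}

toy_config <- function(...) {
  args <- utils::modifyList(list(
    max_iterations = 25L, early_stop_patience = 10L, lr_patience = 5L,
    lr_init = 0.02, batch_size = 32L, seed = 1L
  ), list(...))
  do.call(training_config, args)
}

# one trained toy model, built lazily and reused across tests
.toy_cache <- new.env(parent = emptyenv())

toy_trained <- function(ads = FALSE) {
  key <- if (ads) "ads" else "plain"
  if (is.null(.toy_cache[[key]])) {
    tr <- toy_epochs(30, "train", seed = 1)
    va <- toy_epochs(10, "validation", seed = 2)
    spec <- if (ads) toy_spec(ads = TRUE, seed = 5) else toy_spec(seed = 5)
    m <- build_model(spec, 4, 50)
    .toy_cache[[key]] <- train_model(m, tr, va, toy_config())
  }
  .toy_cache[[key]]
}

# random prediction tensor over ns subjects with ne epochs each
random_tensor <- function(n_members, ns, ne, seed = 1) {
  set.seed(seed)
  probs <- matrix(runif(n_members * ns * ne), n_members, ns * ne)
  prediction_tensor(probs, rep(sprintf("S%02d", seq_len(ns)), each = ne))
}

# independent oracle implementations of the voting rules, written as the
# plainest possible loops over the stated procedure
oracle_epoch_class <- function(p) as.integer(p >= 0.5)

oracle_subject_majority <- function(probs) {
  votes <- oracle_epoch_class(probs)
  n1 <- sum(votes == 1)
  n0 <- sum(votes == 0)
  if (n1 != n0) return(as.integer(n1 > n0))
  as.integer(mean(probs) >= 0.5)
}

oracle_ensemble_subject <- function(mat) {
  verdicts <- integer(nrow(mat))
  for (i in seq_len(nrow(mat))) verdicts[i] <- oracle_subject_majority(mat[i, ])
  n1 <- sum(verdicts == 1)
  n0 <- sum(verdicts == 0)
  if (n1 != n0) return(as.integer(n1 > n0))
  as.integer(mean(mat) >= 0.5)
}

oracle_ensemble_epoch <- function(mat) {
  means <- apply(mat, 2, mean)
  oracle_subject_majority(means)
}

oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_epoch_variance <- function(mat) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    m <- mean(mat[, j])
    acc <- 0
    for (i in seq_len(nrow(mat))) acc <- acc + (mat[i, j] - m)^2
    out[j] <- acc / nrow(mat)
  }
  out
}

band_power_fraction <- function(x, fs, low, high) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$spec[sp$freq >= low & sp$freq <= high]) / sum(sp$spec)
}
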