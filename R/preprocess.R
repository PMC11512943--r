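#' Channel quality control by amplitude standard deviation
#'
#' Flags channels whose amplitude SD exceeds `sd_threshold` (default 75
#' microvolts) or shows no amplitude variation (SD of zero). The rule is
#' applied iteratively — SDs are re-evaluated after each exclusion round
#' until a pass excludes nothing; since exclusion does not alter the
#' remaining signals this converges in one pass, but the loop mirrors the
#' stated procedure and reports `n_iterations`.
#'
#' @param rec An `eeg_recording` with at least one channel and sample.
#' @param sd_threshold Exclusion threshold in microvolts.
#' @return A `channel_qc_report`: tibble of `excluded` channels with
#'   reasons (`high_sd` or `flat`), `per_channel_sd`, `n_iterations`,
#'   `fraction_excluded`.
#' @export
qc_channels <- function(rec, sd_threshold = 75) {
  check_recording(rec)
  if (nrow(rec$data) < 1 || ncol(rec$data) < 2) {
    stop_input("recording must have at least one channel and two samples")
  }
  per_sd <- apply(rec$data, 1, sd)
  excluded <- integer(0)
  reasons <- character(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    candidates <- setdiff(which(per_sd > sd_threshold | per_sd == 0), excluded)
    if (length(candidates) == 0) break
    excluded <- c(excluded, candidates)
    reasons <- c(reasons, ifelse(per_sd[candidates] == 0, "flat", "high_sd"))
  }
  ord <- order(excluded)
  structure(list(
    per_channel_sd = per_sd,
    excluded = tibble(channel = excluded[ord], reason = reasons[ord]),
    n_iterations = n_iter,
    fraction_excluded = length(excluded) / nrow(rec$data)
  ), class = "channel_qc_report")
}

#' @export
print.channel_qc_report <- function(x, ...) {
  cat(sprintf("<channel_qc_report> %d/%d channels excluded (%.1f%%), %d iteration(s)\n",
              nrow(x$excluded), length(x$per_channel_sd),
              100 * x$fraction_excluded, x$n_iterations))
  invisible(x)
}

#' Decide whether a recording is rejected outright
#'
#' A recording is rejected when strictly more than `max_fraction` (default
#' 30%) of its channels were excluded by [qc_channels()].
#'
#' @param report A `channel_qc_report`.
#' @param max_fraction Rejection threshold on the excluded fraction.
#' @return `TRUE` if the recording should be rejected.
#' @export
reject_recording <- function(report, max_fraction = 0.30) {
  if (!inherits(report, "channel_qc_report")) {
    stop_input("report must be a channel_qc_report")
  }
  report$fraction_excluded > max_fraction
}

#' Replace excluded channels by interpolation
#'
#' Substitutes each excluded channel with an inverse-distance-weighted
#' average of its `k` nearest kept channels (Euclidean distance between the
#' unit-sphere electrode positions). Kept channels are unmodified and the
#' output dimensions equal the input's, so downstream models always see the
#' full montage.
#'
#' @param rec An `eeg_recording`.
#' @param excluded Integer channel indices to replace (e.g.
#'   `report$excluded$channel`).
#' @param k Number of nearest kept channels to average.
#' @return The recording with excluded channels replaced.
#' @export
interpolate_channels <- function(rec, excluded, k = 6L) {
  check_recording(rec)
  excluded <- unique(as.integer(excluded))
  if (length(excluded) == 0) return(rec)
  kept <- setdiff(seq_len(nrow(rec$data)), excluded)
  if (length(kept) == 0) {
    stop_input("all channels excluded; nothing to interpolate from")
  }
  pos <- rec$channel_positions
  for (ch in excluded) {
    d <- sqrt(rowSums((pos[kept, , drop = FALSE] -
                       matrix(pos[ch, ], length(kept), 3, byrow = TRUE))^2))
    nn <- kept[order(d)][seq_len(min(k, length(kept)))]
    w <- 1 / pmax(sqrt(rowSums((pos[nn, , drop = FALSE] -
                                matrix(pos[ch, ], length(nn), 3, byrow = TRUE))^2)),
                  1e-12)
    w <- w / sum(w)
    rec$data[ch, ] <- as.numeric(w %*% rec$data[nn, , drop = FALSE])
  }
  rec
}

#' Cut a recording into consecutive 2-second epochs
#'
#' Discards the first `discard_initial_s` seconds (default 30), then cuts
#' the next `extract_s` seconds into consecutive, non-overlapping epochs of
#' `epoch_s` seconds. Epoch windows are half-open `[t, t + epoch_s)`;
#' `extract_s` must be a multiple of `epoch_s`.
#'
#' @param rec An `eeg_recording`.
#' @param extract_s Seconds to extract after the discard.
#' @param role One of `"train"`, `"validation"`, `"test"`.
#' @param epoch_s Epoch length in seconds.
#' @param discard_initial_s Seconds discarded from the start.
#' @param band Band tag carried by the result (`"broadband"` by default).
#' @return An `epoch_array` with `data` `[n_epochs x n_channels x
#'   samples_per_epoch]`, `epoch_onsets` in seconds, `role` and `band`.
#' @export
segment_epochs <- function(rec, extract_s, role = c("train", "validation", "test"),
                           epoch_s = 2, discard_initial_s = 30,
                           band = "broadband") {
  check_recording(rec)
  role <- match.arg(role)
  fs <- rec$sampling_rate
  if (abs(extract_s / epoch_s - round(extract_s / epoch_s)) > 1e-9) {
    stop_config("extract_s must be a whole multiple of epoch_s")
  }
  spe <- round(epoch_s * fs)
  if (abs(epoch_s * fs - spe) > 1e-9) {
    stop_config("epoch_s * sampling_rate must be an integer")
  }
  need <- (discard_initial_s + extract_s) * fs
  if (ncol(rec$data) < need) {
    stop_input(sprintf(
      "recording %s too short: %d samples available, %d required (%.1f s short)",
      rec$subject_id, ncol(rec$data), ceiling(need),
      (need - ncol(rec$data)) / fs))
  }
  n_epochs <- as.integer(round(extract_s / epoch_s))
  offset <- round(discard_initial_s * fs)
  data <- array(0, c(n_epochs, nrow(rec$data), spe))
  for (i in seq_len(n_epochs)) {
    cols <- (offset + (i - 1L) * spe + 1L):(offset + i * spe)
    data[i, , ] <- rec$data[, cols]
  }
  structure(list(
    data = data, subject_id = rec$subject_id, label = rec$label,
    epoch_onsets = discard_initial_s + (seq_len(n_epochs) - 1L) * epoch_s,
    role = role, band = band, sampling_rate = fs
  ), class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %s | %s | %s | %d epochs x %d ch x %d samples\n",
              x$subject_id, x$role, x$band, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3]))
  invisible(x)
}

#' Thin a training epoch array
#'
#' Removes every other epoch from a training array (epochs at even 0-based
#' indices are kept), reducing the correlation between successive training
#' instances. Only valid for `role = "train"`.
#'
#' @param epochs An `epoch_array` with role `"train"`.
#' @return The thinned `epoch_array`.
#' @export
thin_training_epochs <- function(epochs) {
  if (!inherits(epochs, "epoch_array")) stop_input("expected an epoch_array")
  if (epochs$role != "train") {
    stop_config("thinning applies to training epochs only")
  }
  keep <- seq(1L, dim(epochs$data)[1], by = 2L)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$epoch_onsets <- epochs$epoch_onsets[keep]
  epochs
}

#' Stack epoch arrays into a model-ready dataset
#'
#' Collapses one or more `epoch_array`s into a single `eeg_dataset`:
#' an array `x` of `[n_channels x samples_per_epoch x n_epochs]`, labels
#' `y`, and the owning `subject` of every epoch.
#'
#' @param epochs An `epoch_array`, a list of them, or an `eeg_dataset`
#'   (returned unchanged).
#' @return An `eeg_dataset`.
#' @export
as_eeg_dataset <- function(epochs) {
  if (inherits(epochs, "eeg_dataset")) return(epochs)
  if (inherits(epochs, "epoch_array")) epochs <- list(epochs)
  if (!is.list(epochs) || !all(vapply(epochs, inherits, TRUE, "epoch_array"))) {
    stop_input("expected epoch_array objects")
  }
  if (length(epochs) == 0) stop_input("no epochs supplied")
  dims <- dim(epochs[[1]]$data)[2:3]
  n_tot <- sum(vapply(epochs, function(e) dim(e$data)[1], 0L))
  x <- array(0, c(dims[1], dims[2], n_tot))
  y <- integer(n_tot)
  subject <- character(n_tot)
  at <- 0L
  for (e in epochs) {
    ne <- dim(e$data)[1]
    if (!all(dim(e$data)[2:3] == dims)) {
      stop_input("epoch arrays have inconsistent dimensions")
    }
    if (ne > 0) {
      x[, , (at + 1L):(at + ne)] <- aperm(e$data, c(2, 3, 1))
      y[(at + 1L):(at + ne)] <- e$label
      subject[(at + 1L):(at + ne)] <- e$subject_id
      at <- at + ne
    }
  }
  structure(list(x = x, y = y, subject = subject,
                 band = epochs[[1]]$band,
                 sampling_rate = epochs[[1]]$sampling_rate),
            class = "eeg_dataset")
}
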