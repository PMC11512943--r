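#' Specify a synthetic EEG cohort
#'
#' Describes a cohort of resting-state-like multi-channel recordings whose
#' class signal lives in chosen frequency bands. Each channel is a sum of
#' six band-limited stochastic oscillations (white noise shaped into the
#' band in the Fourier domain, random phase, exact target RMS) plus
#' broadband Gaussian noise. The RMS amplitude of the oscillation in band
#' \eqn{b} for a subject of class \eqn{c} is
#' `base_amplitudes[b] * band_effects[[b]][c + 1] * subject_factor`, where
#' the subject factor is log-normal with sigma `subject_sd`. A small
#' fraction of channels is flat (constant zero) or carries inflated
#' broadband noise, emulating the bad channels the quality-control rules
#' target.
#'
#' Class 1 plays the role of "female" and class 0 of "male" throughout the
#' package (the convention fixes the direction of AUC and vote ties).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param class_balance Fraction of class-1 subjects, in (0, 1).
#' @param n_channels Number of channels.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   band edge (45 Hz).
#' @param duration Recording length in seconds; `duration * sampling_rate`
#'   must be an integer.
#' @param band_effects Named list mapping canonical band names to a length-2
#'   numeric `c(class0, class1)` of amplitude multipliers. Bands not listed
#'   keep multiplier 1 for both classes.
#' @param base_amplitudes Named numeric of per-band base RMS amplitudes in
#'   microvolts.
#' @param subject_sd Log-normal sigma of the per-subject amplitude factor.
#' @param noise_sd SD of the additive broadband noise, microvolts.
#' @param p_flat_channel,p_noisy_channel Per-channel probabilities of a flat
#'   or a noisy channel.
#' @param noisy_channel_sd SD of the extra noise added to noisy channels
#'   (chosen above the 75 microvolt QC threshold).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        class_balance = 0.5,
                        n_channels = 129L,
                        sampling_rate = 500,
                        duration = 360,
                        band_effects = list(),
                        base_amplitudes = c(delta = 20, theta = 12, alpha = 15,
                                            low_beta = 8, high_beta = 6,
                                            gamma = 5),
                        subject_sd = 0.2,
                        noise_sd = 5,
                        p_flat_channel = 0.02,
                        p_noisy_channel = 0.02,
                        noisy_channel_sd = 100,
                        seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    stop_config("n_subjects must be an integer >= 2")
  }
  if (!is_scalar_number(class_balance) || class_balance <= 0 || class_balance >= 1) {
    stop_config("class_balance must lie strictly between 0 and 1")
  }
  if (!is_count(n_channels)) stop_config("n_channels must be a positive integer")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_config("sampling_rate must be positive")
  }
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_config("duration must be positive")
  }
  if (abs(duration * sampling_rate - round(duration * sampling_rate)) > 1e-9) {
    stop_config("duration * sampling_rate must be an integer number of samples")
  }
  bad <- setdiff(names(band_effects), band_names())
  if (length(bad) > 0) {
    stop_config(sprintf("band_effects names not canonical: %s",
                        paste(bad, collapse = ", ")))
  }
  if (sampling_rate <= 2 * 45) {
    stop_config("sampling_rate must exceed twice the highest band edge (90 Hz)")
  }
  for (nm in names(band_effects)) {
    be <- band_effects[[nm]]
    if (!is.numeric(be) || length(be) != 2 || any(be < 0)) {
      stop_config(sprintf("band_effects[['%s']] must be c(class0, class1) >= 0", nm))
    }
  }
  if (!all(band_names() %in% names(base_amplitudes))) {
    stop_config("base_amplitudes must name all six canonical bands")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), class_balance = class_balance,
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    duration = duration, band_effects = band_effects,
    base_amplitudes = base_amplitudes, subject_sd = subject_sd,
    noise_sd = noise_sd, p_flat_channel = p_flat_channel,
    p_noisy_channel = p_noisy_channel, noisy_channel_sd = noisy_channel_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

new_recording <- function(subject_id, label, data, sampling_rate,
                          channel_positions) {
  structure(list(
    subject_id = subject_id, label = as.integer(label), data = data,
    sampling_rate = sampling_rate, channel_positions = channel_positions
  ), class = "eeg_recording")
}

check_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop_input("expected an eeg_recording")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s | label %d | %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}

# quasi-uniform electrode positions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  pos <- cbind(r * cos(phi), r * sin(phi), z, deparse.level = 0)
  pos / sqrt(rowSums(pos^2))
}

# one channel: Hermitian spectrum with per-band scaling, single inverse FFT.
# freq_idx: list of in-band positive-frequency indices per band;
# amps: per-band target RMS. Returns the time series.
synth_channel <- function(n, freq_idx, amps) {
  half <- (n - 1L) %/% 2L
  zr <- rnorm(half)
  zi <- rnorm(half)
  scale <- numeric(half)
  for (b in seq_along(freq_idx)) {
    idx <- freq_idx[[b]]
    if (length(idx) == 0 || amps[b] <= 0) next
    pw <- sum(zr[idx]^2 + zi[idx]^2)
    if (pw > 0) scale[idx] <- amps[b] * n / sqrt(2 * pw)
  }
  zfull <- complex(length.out = n)
  zk <- complex(real = zr * scale, imaginary = zi * scale)
  zfull[2L:(half + 1L)] <- zk
  zfull[n:(n - half + 1L)] <- Conj(zk)
  Re(stats::fft(zfull, inverse = TRUE)) / n
}

#' Generate a synthetic cohort
#'
#' Deterministically expands a [cohort_spec()] into a list of recordings.
#' Class counts follow `class_balance` rounded to the nearest integer; the
#' same spec (including seed) always regenerates a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `eeg_recording` objects.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_subjects
  fs <- spec$sampling_rate
  ns <- as.integer(round(spec$duration * fs))
  n1 <- as.integer(round(n * spec$class_balance))
  labels <- integer(n)
  labels[sample.int(n, n1)] <- 1L
  positions <- fibonacci_sphere(spec$n_channels)

  tab <- eeg_bands()
  half <- (ns - 1L) %/% 2L
  freqs <- seq_len(half) * fs / ns
  freq_idx <- lapply(seq_len(nrow(tab)), function(i) {
    which(freqs >= tab$low[i] & freqs <= tab$high[i])
  })
  mult <- function(band, cls) {
    be <- spec$band_effects[[band]]
    if (is.null(be)) 1 else be[cls + 1L]
  }

  lapply(seq_len(n), function(s) {
    cls <- labels[s]
    subj_factor <- exp(rnorm(1, 0, spec$subject_sd))
    amps <- vapply(seq_len(nrow(tab)), function(i) {
      spec$base_amplitudes[[tab$band[i]]] * mult(tab$band[i], cls) * subj_factor
    }, 0)
    u <- runif(spec$n_channels)
    flat <- u < spec$p_flat_channel
    noisy <- !flat & u < spec$p_flat_channel + spec$p_noisy_channel
    data <- matrix(0, spec$n_channels, ns)
    for (ch in seq_len(spec$n_channels)) {
      x <- synth_channel(ns, freq_idx, amps) + rnorm(ns, 0, spec$noise_sd)
      if (flat[ch]) {
        x <- numeric(ns)
      } else if (noisy[ch]) {
        x <- x + rnorm(ns, 0, spec$noisy_channel_sd)
      }
      data[ch, ] <- x
    }
    new_recording(sprintf("S%04d", s), cls, data, fs, positions)
  })
}
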