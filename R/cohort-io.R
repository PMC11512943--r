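# Cohort persistence.
#
# A cohort directory holds one signal file per subject plus `manifest.csv`
# (subject_id, label, path, sampling_rate) and a JSON sidecar per subject
# carrying the channel positions. Two signal dialects:
#   * "edf" — European Data Format (16-bit, 1-second data records); lossless
#     to within the 16-bit physical/digital quantization of the format.
#   * "csv" — plain-text samples x channels table; lossless to double
#     precision printing.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

write_edf <- function(rec, path) {
  data <- rec$data
  nch <- nrow(data)
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop_io("EDF writing requires an integer sampling rate per 1-second record")
  }
  fs <- as.integer(round(fs))
  n_rec <- ncol(data) %/% fs
  if (n_rec * fs != ncol(data)) {
    stop_io("EDF writing requires a whole number of 1-second records")
  }
  pmax_ <- pmax(apply(abs(data), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("synthetic EEG cohort", 80),
    pad_field("01.01.20", 8),
    pad_field("00.00.00", 8),
    pad_field(256L * (nch + 1L), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(nch, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(seq_len(nch), function(i) pad_field(sprintf("EEG %03d", i), 16), ""), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field("uV", 8), nch), collapse = ""),
    paste(vapply(pmax_, function(p) pad_field(sprintf("%.6g", -p), 8), ""), collapse = ""),
    paste(vapply(pmax_, function(p) pad_field(sprintf("%.6g", p), 8), ""), collapse = ""),
    paste(rep(pad_field("-32767", 8), nch), collapse = ""),
    paste(rep(pad_field("32767", 8), nch), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field(fs, 8), nch), collapse = ""),
    paste(rep(pad_field("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  # re-read the physical extrema exactly as a reader will parse them, so the
  # digitization is consistent with the stored ASCII header
  pmax_parsed <- as.numeric(sprintf("%.6g", pmax_))
  dig <- matrix(0L, nch, ncol(data))
  for (i in seq_len(nch)) {
    dig[i, ] <- as.integer(round(data[i, ] / pmax_parsed[i] * 32767))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE]))[seq_len(nch * fs)],
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(wd) trimws(readChar(con, wd, useBytes = TRUE))
  rd(8)                      # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  vapply(seq_len(nch), function(i) rd(80), "")
  vapply(seq_len(nch), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  vapply(seq_len(nch), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  vapply(seq_len(nch), function(i) rd(32), "")
  if (length(unique(spr)) != 1) {
    stop_io("EDF reader supports a single sampling rate across channels")
  }
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nch * spr[1], size = 2L,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, spr[1], nch)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(nch)) {
    data[i, ] <- phys_min[i] + (data[i, ] - dig_min[i]) * gain[i]
  }
  list(patient = patient, data = data, sampling_rate = spr[1] / rec_dur,
       labels = labels)
}

#' Write a cohort to a directory
#'
#' Writes one signal file per subject (`edf` or `csv` dialect), a JSON
#' sidecar with channel positions and label, and a `manifest.csv` listing
#' `subject_id, label, path, sampling_rate`.
#'
#' @param recordings A list of `eeg_recording` objects.
#' @param directory Output directory (created if needed).
#' @param dialect `"edf"` (default) or `"csv"`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(recordings, directory, dialect = c("edf", "csv")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  rows <- lapply(recordings, function(rec) {
    check_recording(rec)
    fname <- sprintf("%s.%s", rec$subject_id, dialect)
    path <- file.path(directory, fname)
    if (dialect == "edf") {
      write_edf(rec, path)
    } else {
      dt <- data.table::as.data.table(t(rec$data))
      data.table::setnames(dt, sprintf("ch%03d", seq_len(nrow(rec$data))))
      data.table::fwrite(dt, path)
    }
    sidecar <- file.path(directory, sprintf("%s.json", rec$subject_id))
    jsonlite::write_json(list(
      subject_id = rec$subject_id, label = rec$label,
      sampling_rate = rec$sampling_rate,
      channel_positions = unname(apply(rec$channel_positions, 1, as.numeric,
                                       simplify = FALSE))
    ), sidecar, auto_unbox = TRUE, digits = NA)
    tibble(subject_id = rec$subject_id, label = rec$label, path = fname,
           sampling_rate = rec$sampling_rate)
  })
  manifest <- dplyr::bind_rows(rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort directory
#'
#' Reads the manifest written by [write_cohort()] and reconstructs the
#' recordings. A manifest entry whose signal file is missing raises an I/O
#' error naming the subject.
#'
#' @param directory Cohort directory.
#' @return A list of `eeg_recording` objects.
#' @export
read_cohort <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) {
    stop_io(sprintf("no manifest.csv in %s", directory))
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    path <- file.path(directory, manifest$path[i])
    if (!file.exists(path)) {
      stop_io(sprintf("signal file for subject %s is missing (%s)", sid, path))
    }
    sidecar <- file.path(directory, sprintf("%s.json", sid))
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
    if (grepl("\\.edf$", path)) {
      edf <- read_edf(path)
      data <- edf$data
    } else {
      dt <- data.table::fread(path)
      data <- t(as.matrix(dt))
      dimnames(data) <- NULL
    }
    pos <- if (!is.null(meta)) {
      do.call(rbind, lapply(meta$channel_positions, as.numeric))
    } else {
      fibonacci_sphere(nrow(data))
    }
    new_recording(sid, manifest$label[i], data, manifest$sampling_rate[i], pos)
  })
}
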