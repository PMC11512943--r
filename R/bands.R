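#' Canonical EEG frequency bands
#'
#' The six-band table used throughout the package: delta 0.5--4 Hz,
#' theta 4--8 Hz, alpha 8--12 Hz, low-beta 12--20 Hz, high-beta 20--30 Hz
#' and gamma 30--45 Hz. Band-limited synthesis, band decomposition and the
#' frequency ensemble all draw their edges from this table.
#'
#' @return A tibble with columns `band`, `low` and `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "low_beta", "high_beta", "gamma"),
    low  = c(0.5, 4, 8, 12, 20, 30),
    high = c(4, 8, 12, 20, 30, 45)
  )
}

band_names <- function() eeg_bands()$band

band_edges <- function(band) {
  tab <- eeg_bands()
  i <- match(band, tab$band)
  if (is.na(i)) {
    stop_config(sprintf(
      "unknown frequency band '%s'; canonical bands are %s",
      band, paste(tab$band, collapse = ", ")
    ))
  }
  c(low = tab$low[i], high = tab$high[i])
}
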