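# internal helpers shared across modules

stop_input <- function(msg, class = "eegensemble_input_error") {
  abort(msg, class = c(class, "eegensemble_error"))
}

stop_config <- function(msg) {
  stop_input(msg, class = "eegensemble_config_error")
}

stop_io <- function(msg) {
  stop_input(msg, class = "eegensemble_io_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 65537) %% 2147483647)
}

`%||%` <- rlang::`%||%`
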