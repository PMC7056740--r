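#' @keywords internal
"_PACKAGE"

# Structured conditions so the CLI can map failures onto exit codes
# (2 validation, 3 format, 4 numerical).

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("tcd4_validation_error", "tcd4_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("tcd4_format_error", "tcd4_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("tcd4_numerical_error", "tcd4_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
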