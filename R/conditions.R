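# Structured conditions so callers (and the CLI) can distinguish bad input
# from internal failure.

ar_stop <- function(msg, class, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "ar_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

#' @noRd
stop_validation <- function(msg) ar_stop(msg, "ar_validation_error")

#' @noRd
stop_format <- function(msg) ar_stop(msg, "ar_format_error")

# Internal numeric tolerance for "is this an integer grid index".
.grid_tol <- 1e-8
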