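# Structured error conditions. Every error raised by grnscore carries the
# class "grnscore_error" plus a specific subclass so callers (and the CLI)
# can dispatch on the failure kind rather than on message text.

stop_grn <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "grnscore_error"), call = call))
}

#' @keywords internal
parse_error <- function(message) stop_grn("grn_parse_error", message)

#' @keywords internal
self_loop_error <- function(message) stop_grn("grn_self_loop_error", message)
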