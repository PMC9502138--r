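# Classed conditions so callers (and the CLI) can distinguish bad user input
# from transport failures from malformed payloads.

litsim_error <- function(message, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "litsim_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_validation <- function(message, ...) {
  stop(litsim_error(message, "litsim_validation_error", ...))
}

stop_input_format <- function(message, ...) {
  stop(litsim_error(message, "litsim_input_error", ...))
}

stop_retrieval <- function(message, ...) {
  stop(litsim_error(message, "litsim_retrieval_error", ...))
}

stop_parse <- function(message, ...) {
  stop(litsim_error(message, "litsim_parse_error", ...))
}
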