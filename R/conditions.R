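# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string-matching messages.

stop_config <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("pdnet_config_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_validation <- function(msg, problems = NULL) {
  cond <- structure(
    class = c("pdnet_validation_error", "error", "condition"),
    list(message = msg, call = NULL, problems = problems)
  )
  stop(cond)
}

stop_empty <- function(msg) {
  stop(structure(
    class = c("pdnet_empty_result", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
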