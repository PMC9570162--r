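# Classed conditions so callers (and the CLI) can map failure kinds to
# exit codes without string-matching messages.

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "contigdot_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_param <- function(msg, ...) stop_with("contigdot_parameter_error", msg, ...)
stop_format <- function(msg, ...) stop_with("contigdot_format_error", msg, ...)
stop_io <- function(msg, ...) stop_with("contigdot_io_error", msg, ...)
stop_usage <- function(msg, ...) stop_with("contigdot_usage_error", msg, ...)
stop_consistency <- function(msg, ...) stop_with("contigdot_consistency_error", msg, ...)
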