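## Structured conditions so callers can distinguish failure modes
## programmatically (tryCatch on the class) instead of grepping messages.

lcbnError <- function(class, message, call = sys.call(-1), ...) {
  structure(
    class = c(class, "lcbnError", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stopLcbn <- function(class, message, ...) {
  stop(lcbnError(class, message, ...))
}

lcbnWarning <- function(class, message, ...) {
  warning(structure(
    class = c(class, "lcbnWarning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
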