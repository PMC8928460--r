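# Structured error conditions. Every error raised by the package carries a
# subclass of "structatlas_error" so callers can handle failure modes
# programmatically rather than by matching message text.

sa_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "structatlas_error")))
}

sa_check <- function(ok, class, message) {
  if (!isTRUE(ok)) sa_abort(class, message)
  invisible(TRUE)
}
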