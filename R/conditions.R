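## Structured condition classes so callers can distinguish failure modes
## (channel vs format vs integrity ...) without matching message text.

.cytoloopError <- function(subclass, message, ..., call = sys.call(-1)) {
  structure(
    class = c(subclass, "cytoloop_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stopChannelError <- function(channel, message = NULL) {
  msg <- message %||% sprintf("required channel '%s' is absent after channel mapping", channel)
  stop(.cytoloopError("cytoloop_channel_error", msg, channel = channel))
}

stopFormatError <- function(message) {
  stop(.cytoloopError("cytoloop_format_error", message))
}

stopIntegrityError <- function(message) {
  stop(.cytoloopError("cytoloop_integrity_error", message))
}

stopValidationError <- function(message) {
  stop(.cytoloopError("cytoloop_validation_error", message))
}

stopOrderingError <- function(message) {
  stop(.cytoloopError("cytoloop_ordering_error", message))
}

stopConsistencyError <- function(message) {
  stop(.cytoloopError("cytoloop_consistency_error", message))
}

stopIOError <- function(message) {
  stop(.cytoloopError("cytoloop_io_error", message))
}

stopConfigError <- function(message) {
  stop(.cytoloopError("cytoloop_config_error", message))
}

stopActuatorError <- function(message) {
  stop(.cytoloopError("cytoloop_actuator_error", message))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
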