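## Pluggable pump back-ends. A pump receives rate commands in mL/hr through
## the actuate() generic; the controller never talks to hardware directly.

#' MockPump: records commanded rates
#'
#' An actuator that records every commanded rate (with a command counter)
#' instead of driving hardware; used in tests and in simulate/analyze modes.
#'
#' @slot env environment holding the command record (reference semantics so
#'   the same pump object observes all commands).
#' @export
setClass("MockPump", representation(env = "environment"))

#' @rdname MockPump-class
#' @return A \code{MockPump}.
#' @export
MockPump <- function() {
  e <- new.env(parent = emptyenv())
  e$rates <- numeric(0)
  new("MockPump", env = e)
}

#' Commanded-rate history of a MockPump
#' @param pump a \linkS4class{MockPump}.
#' @return Numeric vector of rates in command order.
#' @export
commandedRates <- function(pump) pump@env$rates

#' SerialPump: text-protocol pump over an R connection
#'
#' Speaks the line protocol \code{"RATE <ml_per_hr>\\n"} and expects an
#' \code{"OK\\n"} acknowledgment within \code{timeout} seconds. On a missing
#' or wrong acknowledgment the command is retried once; a second failure
#' raises an actuator alarm (callers treat the pump as stopped). The
#' connection is any open read/write R connection — a serial device file
#' (e.g. \code{file("/dev/ttyACM0", "r+b")}) or a socket.
#'
#' @slot con an open R connection.
#' @slot timeout acknowledgment timeout in seconds.
#' @export
setClass("SerialPump", representation(con = "ANY", timeout = "numeric"),
         prototype(timeout = 2))

#' @rdname SerialPump-class
#' @param con open read/write connection to the pump.
#' @param timeout acknowledgment timeout (seconds).
#' @return A \code{SerialPump}.
#' @export
SerialPump <- function(con, timeout = 2) {
  new("SerialPump", con = con, timeout = timeout)
}

#' Command a pump rate
#'
#' @param pump an actuator (\linkS4class{MockPump} or
#'   \linkS4class{SerialPump}).
#' @param rate pump rate in mL/hr (>= 0; 0 means stop).
#' @return \code{TRUE} invisibly on success; a \code{SerialPump} signals a
#'   \code{cytoloop_actuator_error} after one failed retry.
#' @rdname actuate
#' @export
setMethod("actuate", signature("MockPump", "numeric"), function(pump, rate) {
  if (rate < 0) stopValidationError("pump rate must be >= 0")
  pump@env$rates <- c(pump@env$rates, rate)
  invisible(TRUE)
})

#' @rdname actuate
#' @export
setMethod("actuate", signature("SerialPump", "numeric"), function(pump, rate) {
  if (rate < 0) stopValidationError("pump rate must be >= 0")
  tryOnce <- function() {
    writeLines(sprintf("RATE %g", rate), pump@con)
    flush(pump@con)
    identical(.readLineTimeout(pump@con, pump@timeout), "OK")
  }
  if (tryOnce()) return(invisible(TRUE))
  if (tryOnce()) return(invisible(TRUE))
  stopActuatorError(sprintf(
    "no acknowledgment for 'RATE %g' after retry (timeout %gs); assuming pump stopped",
    rate, pump@timeout))
})

## Poll a (possibly non-blocking) connection for one line until the deadline.
.readLineTimeout <- function(con, timeout) {
  deadline <- Sys.time() + timeout
  repeat {
    ln <- tryCatch(readLines(con, n = 1L), error = function(e) character(0))
    if (length(ln)) return(trimws(ln[1]))
    if (Sys.time() >= deadline) return(NULL)
    Sys.sleep(0.01)
  }
}
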