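#' Evaluate the feed-pump state machine on one sample
#'
#' Applies the decision rules, in strict priority order, to one new usable
#' sample's statistics:
#' \enumerate{
#'   \item \strong{Safeguard} (highest priority): if the slope of the
#'     smoothed percent-PI series is positive, or the smoothed percent PI
#'     exceeds \code{piMax}, the pump is commanded off
#'     (\code{cause = "safeguard_stop"}), regardless of the MFI signal.
#'   \item \strong{Start}: pump off, safeguard clear, and the MFI slope is
#'     defined and strictly negative: the pump starts at the bottom of the
#'     rate ladder (\code{cause = "induction_decline_start"}).
#'   \item \strong{Escalate}: pump on, safeguard clear, at least
#'     \code{dwellSamples} usable samples at the current rate, MFI slope
#'     defined and strictly negative, and not at the top of the ladder: the
#'     rate moves up exactly one position (\code{cause = "escalate"}).
#'   \item \strong{Hold}: otherwise the rate is unchanged.
#' }
#' A slope of exactly zero is non-negative and never triggers; an undefined
#' slope (fewer than k points) always resolves to hold. After a non-latching
#' safeguard stop the pump may restart — from the bottom of the ladder — once
#' the safeguard clears and the MFI slope is again negative.
#'
#' @param state a \linkS4class{ControllerState}.
#' @param stats a usable \linkS4class{PopulationStats} (callers skip and log
#'   unusable samples).
#' @param cfg a \linkS4class{ControllerConfig}.
#' @return A list with elements \code{state} (updated
#'   \code{ControllerState}), \code{command} (one-row data.frame with
#'   \code{t}, \code{rate}, \code{cause}) and \code{audit} (named list: the
#'   signals and thresholds behind the decision).
#' @rdname evaluateController
#' @export
setMethod("evaluateController",
          signature("ControllerState", "PopulationStats", "ControllerConfig"),
function(state, stats, cfg) {
  prevRate <- if (state@pumpOn) cfg@rateLadder[state@ladderIndex] else 0

  if (stats@mfiDefined)
    state@mfiTrend <- emaAppend(state@mfiTrend, stats@t, stats@mfiGfp)
  if (!is.na(stats@pctPi))
    state@piTrend <- emaAppend(state@piTrend, stats@t, stats@pctPi)

  mfiSlope <- slopeLastK(state@mfiTrend)
  piSlope <- slopeLastK(state@piTrend)
  nPi <- length(state@piTrend@ema)
  piAvg <- if (cfg@piAverage == "ema") {
    if (nPi > 0) state@piTrend@ema[nPi] else NA_real_
  } else .lastKMean(state@piTrend)

  safeguardNow <- isTRUE(piSlope > 0) || isTRUE(piAvg > cfg@piMax)
  if (cfg@safeguardLatching) {
    state@safeguardActive <- state@safeguardActive || safeguardNow
  } else {
    state@safeguardActive <- safeguardNow
  }

  if (safeguardNow || (cfg@safeguardLatching && state@safeguardActive)) {
    state@pumpOn <- FALSE
    cause <- "safeguard_stop"
    rate <- 0
  } else if (!state@pumpOn && isTRUE(mfiSlope < 0)) {
    state@pumpOn <- TRUE
    state@ladderIndex <- 1L
    cause <- "induction_decline_start"
    rate <- cfg@rateLadder[1]
  } else if (state@pumpOn && state@samplesAtRate >= cfg@dwellSamples &&
             isTRUE(mfiSlope < 0) &&
             state@ladderIndex < length(cfg@rateLadder)) {
    state@ladderIndex <- state@ladderIndex + 1L
    cause <- "escalate"
    rate <- cfg@rateLadder[state@ladderIndex]
  } else {
    cause <- "hold"
    rate <- prevRate
  }
  state@samplesAtRate <-
    if (rate != prevRate) 0L else state@samplesAtRate + 1L

  audit <- list(
    t = stats@t, sample_id = stats@sampleId,
    mfi = if (stats@mfiDefined) stats@mfiGfp else NA_real_,
    mfi_ema = if (length(state@mfiTrend@ema))
                state@mfiTrend@ema[length(state@mfiTrend@ema)] else NA_real_,
    mfi_slope = mfiSlope,
    pct_pi = stats@pctPi, pct_pi_ema = piAvg, pi_slope = piSlope,
    pi_max = cfg@piMax, cause = cause, rate = rate
  )
  list(state = state,
       command = data.frame(t = stats@t, rate = rate, cause = cause,
                            stringsAsFactors = FALSE),
       audit = audit)
})

#' Run the controller over an ordered stream of sample statistics
#'
#' Folds \code{\link{evaluateController}} over the stream. Unusable samples
#' (too few gated events) are never fed to the decision rules: they are
#' skipped and recorded in the audit trail with \code{cause =
#' "skip_unusable"}. Every evaluation appends one audit record binding the
#' commanded rate to the smoothed signals and slopes that caused it;
#' replaying the audit log reproduces the command sequence exactly.
#'
#' @param stream a list of \linkS4class{PopulationStats}, or a data.frame
#'   with columns \code{t}, \code{mfi_gfp}, \code{pct_pi}, \code{usable}
#'   (and optionally \code{sample_id}), in strictly increasing time order.
#' @param cfg a \linkS4class{ControllerConfig}.
#' @param state starting \linkS4class{ControllerState}; a fresh one by
#'   default.
#' @param alpha,k,slopeOn trend parameters used when \code{state} is not
#'   supplied.
#' @param auditPath optional path: audit records are appended as JSON lines.
#' @return A list with \code{commands} (data.frame of t/rate/cause, one row
#'   per evaluated sample), \code{audit} (list of audit records) and
#'   \code{state} (final controller state).
#' @export
runSession <- function(stream, cfg = ControllerConfig(), state = NULL,
                       alpha = 0.5, k = 3L, slopeOn = "ema",
                       auditPath = NULL) {
  if (is.data.frame(stream)) stream <- .statsFromFrame(stream)
  if (is.null(state)) state <- ControllerState(alpha = alpha, k = k,
                                               slopeOn = slopeOn)
  tPrev <- if (length(state@piTrend@times))
             max(state@piTrend@times) else -Inf
  if (length(state@mfiTrend@times))
    tPrev <- max(tPrev, max(state@mfiTrend@times))

  commands <- vector("list", length(stream))
  audit <- vector("list", length(stream))
  nc <- 0L
  for (stats in stream) {
    if (stats@t <= tPrev)
      stopOrderingError(sprintf(
        "out-of-order sample at t = %.6g h (previous %.6g h)", stats@t, tPrev))
    tPrev <- stats@t
    nc <- nc + 1L
    if (!stats@usable) {
      audit[[nc]] <- list(t = stats@t, sample_id = stats@sampleId,
                          mfi = NA_real_, mfi_ema = NA_real_,
                          mfi_slope = NA_real_, pct_pi = stats@pctPi,
                          pct_pi_ema = NA_real_, pi_slope = NA_real_,
                          pi_max = cfg@piMax, cause = "skip_unusable",
                          rate = NA_real_)
      commands[nc] <- list(NULL)
      next
    }
    res <- evaluateController(state, stats, cfg)
    state <- res$state
    commands[[nc]] <- res$command
    audit[[nc]] <- res$audit
  }
  audit <- audit[seq_len(nc)]
  if (!is.null(auditPath)) writeAuditLog(audit, auditPath, append = TRUE)
  cmds <- do.call(rbind, commands[!vapply(commands, is.null, logical(1))])
  if (is.null(cmds))
    cmds <- data.frame(t = numeric(0), rate = numeric(0),
                       cause = character(0), stringsAsFactors = FALSE)
  list(commands = cmds, audit = audit, state = state)
}

.statsFromFrame <- function(df) {
  need <- c("t", "mfi_gfp", "pct_pi", "usable")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopConsistencyError(paste("stats data.frame lacks column(s):",
                               paste(missing, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    mfi <- df$mfi_gfp[i]
    n <- if ("n_total" %in% names(df)) as.integer(df$n_total[i]) else 1000L
    new("PopulationStats",
        sampleId = if ("sample_id" %in% names(df))
                     as.character(df$sample_id[i]) else sprintf("s%04d", i),
        t = df$t[i], nTotal = n, nDebris = 0L, nDamaged = 0L,
        nIntactGfpPos = n, nIntactGfpNeg = 0L,
        mfiGfp = if (is.na(mfi)) NA_real_ else mfi,
        mfiDefined = !is.na(mfi),
        pctPi = df$pct_pi[i], usable = isTRUE(df$usable[i]))
  })
}

#' Write audit records as JSON lines
#'
#' One JSON object per evaluation; the audit log is the single source of
#' truth for why the pump rate changed. Identical statistic streams produce
#' byte-identical logs (no wall-clock content; the time stamp is the sample's
#' acquisition time in hours).
#'
#' @param records list of audit records (from \code{\link{runSession}}).
#' @param path output path.
#' @param append append to an existing log (default FALSE).
#' @return \code{path}, invisibly.
#' @export
writeAuditLog <- function(records, path, append = FALSE) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  na = "null")),
    character(1))
  con <- file(path, open = if (append) "ab" else "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Read an audit log and recover the command sequence
#'
#' @param path JSON-lines audit log.
#' @return A list with \code{records} (list of parsed records) and
#'   \code{commands} (data.frame of t/rate/cause for the evaluated samples).
#' @export
readAuditLog <- function(path) {
  if (!file.exists(path)) stopIOError(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  records <- lapply(lines, jsonlite::fromJSON)
  keep <- vapply(records, function(r) r$cause != "skip_unusable", logical(1))
  cmds <- if (any(keep)) {
    do.call(rbind, lapply(records[keep], function(r)
      data.frame(t = as.numeric(r$t), rate = as.numeric(r$rate),
                 cause = r$cause, stringsAsFactors = FALSE)))
  } else {
    data.frame(t = numeric(0), rate = numeric(0), cause = character(0),
               stringsAsFactors = FALSE)
  }
  list(records = records, commands = cmds)
}
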