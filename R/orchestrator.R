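## The three workflows: live control over a watched directory, offline batch
## analysis, and in-silico experiments. All are thin compositions of the
## fcs/gating/trend/controller/simulator layers.

.STATS_HEADER <- c("sample_id", "t", "n_total", "n_debris", "n_damaged",
                   "n_intact_gfp_pos", "n_intact_gfp_neg", "mfi_gfp",
                   "pct_pi", "usable", "mfi_ema", "pi_ema")

.emptyStatsFrame <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(logical(0)), length(.STATS_HEADER)), .STATS_HEADER))
  df
}

#' Offline batch analysis of an FCS directory
#'
#' Reads every FCS file in \code{inDir} in acquisition-time order, gates and
#' summarizes each sample, updates the trend series, and writes the
#' monitoring time series (one CSV row per sample) plus per-sample FL1-H
#' histogram data. No actuation. Malformed files are logged and skipped;
#' re-running on the same directory yields an identical CSV.
#'
#' @param inDir directory of FCS files.
#' @param gate a \linkS4class{GateConfig}.
#' @param statsCsv output CSV path (overwritten); NULL to skip writing.
#' @param histCsv optional output CSV of per-sample FL1-H histogram data
#'   (columns sample_id, t, bin_lo, bin_hi, count).
#' @param channelMap,t0 passed to \code{\link{readFCS}}.
#' @param alpha,k,slopeOn trend parameters.
#' @param histBreaks number of log-spaced histogram bins.
#' @param logFun function(level, msg, ...) for status logging.
#' @return The statistics data.frame (with \code{mfi_ema}, \code{pi_ema}
#'   columns), invisibly.
#' @export
runAnalyze <- function(inDir, gate = GateConfig(), statsCsv = NULL,
                       histCsv = NULL, channelMap = NULL, t0 = NULL,
                       alpha = 0.5, k = 3L, slopeOn = "ema", histBreaks = 50,
                       logFun = .logLine) {
  paths <- discoverNewSamples(inDir, character(), t0 = t0)
  mfiTrend <- TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn)
  piTrend <- TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn)
  rows <- list()
  hists <- list()
  for (pth in paths) {
    tab <- tryCatch(readFCS(pth, channelMap = channelMap, t0 = t0),
                    cytoloop_error = function(e) {
                      logFun("warn", "skipping malformed FCS file",
                             file = pth, reason = conditionMessage(e))
                      NULL
                    })
    if (is.null(tab)) next
    st <- summarizeSample(tab, classifyEvents(tab, gate), gate)
    if (st@mfiDefined) mfiTrend <- emaAppend(mfiTrend, st@t, st@mfiGfp)
    if (!is.na(st@pctPi)) piTrend <- emaAppend(piTrend, st@t, st@pctPi)
    row <- as.data.frame(st)
    row$mfi_ema <- if (length(mfiTrend@ema))
      mfiTrend@ema[length(mfiTrend@ema)] else NA_real_
    row$pi_ema <- if (length(piTrend@ema))
      piTrend@ema[length(piTrend@ema)] else NA_real_
    rows[[length(rows) + 1L]] <- row

    if (!is.null(histCsv)) {
      fl1 <- eventMatrix(tab)[, "FL1-H"]
      fl1 <- fl1[fl1 > 0]
      if (length(fl1)) {
        brk <- exp(seq(log(max(min(fl1), 1e-3)), log(max(fl1) + 1e-9),
                       length.out = histBreaks + 1))
        h <- graphics::hist(fl1, breaks = brk, plot = FALSE)
        hists[[length(hists) + 1L]] <- data.frame(
          sample_id = sampleId(tab), t = acquiredAt(tab),
          bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
          count = h$counts)
      }
    }
  }
  stats <- if (length(rows)) do.call(rbind, rows) else .emptyStatsFrame()
  if (!is.null(statsCsv))
    utils::write.csv(stats, statsCsv, row.names = FALSE)
  if (!is.null(histCsv)) {
    hdf <- if (length(hists)) do.call(rbind, hists)
           else data.frame(sample_id = character(0), t = numeric(0),
                           bin_lo = numeric(0), bin_hi = numeric(0),
                           count = integer(0))
    utils::write.csv(hdf, histCsv, row.names = FALSE)
  }
  invisible(stats)
}

#' Rebuild controller state from persisted artifacts
#'
#' Reconstructs the trend series from the EMA columns of an existing
#' statistics CSV (persisted values, not re-smoothed from raw) and the pump
#' state from the last audit-log command, so a restarted control session
#' resumes exactly where the previous one stopped.
#'
#' @param statsCsv statistics CSV written by a previous session.
#' @param auditPath JSON-lines audit log of the previous session (optional).
#' @param cfg a \linkS4class{ControllerConfig}.
#' @param alpha,k,slopeOn trend parameters.
#' @return A \linkS4class{ControllerState}.
#' @export
resumeControllerState <- function(statsCsv, auditPath = NULL,
                                  cfg = ControllerConfig(),
                                  alpha = 0.5, k = 3L, slopeOn = "ema") {
  state <- ControllerState(alpha = alpha, k = k, slopeOn = slopeOn)
  if (file.exists(statsCsv)) {
    df <- utils::read.csv(statsCsv, stringsAsFactors = FALSE)
    okM <- !is.na(df$mfi_gfp) & !is.na(df$mfi_ema)
    state@mfiTrend <- trendFromValues(df$t[okM], df$mfi_gfp[okM],
                                      df$mfi_ema[okM], alpha, k, slopeOn)
    okP <- !is.na(df$pct_pi) & !is.na(df$pi_ema)
    state@piTrend <- trendFromValues(df$t[okP], df$pct_pi[okP],
                                     df$pi_ema[okP], alpha, k, slopeOn)
  }
  if (!is.null(auditPath) && file.exists(auditPath)) {
    cmds <- readAuditLog(auditPath)$commands
    if (nrow(cmds)) {
      rates <- cmds$rate
      last <- rates[length(rates)]
      state@pumpOn <- last > 0
      state@ladderIndex <-
        if (last > 0) as.integer(match(last, cfg@rateLadder)) else 0L
      changes <- which(diff(c(0, rates)) != 0)
      state@samplesAtRate <- as.integer(length(rates) -
        (if (length(changes)) max(changes) else 0L))
      state@safeguardActive <-
        cmds$cause[length(rates)] == "safeguard_stop"
    }
  }
  state
}

#' Live control loop over a watched directory
#'
#' Polls \code{watchDir} for new FCS files; for each one runs
#' read -> gate -> summarize -> trend append -> controller evaluate ->
#' actuate, appending to the statistics CSV and the audit log. Malformed
#' files are quarantined (moved to \code{quarantineDir}) and the loop
#' continues; an actuator alarm is logged and the pump assumed stopped. On
#' shutdown — \code{maxPolls} exhausted, or an interrupt — the pump is
#' commanded to rate 0 and a final rate-0 audit record is written. When
#' \code{resume = TRUE} and artifacts from a previous session exist, trend
#' and pump state are reconstructed from them first.
#'
#' @param watchDir directory the acquisition software drops FCS files into.
#' @param gate,cfg gate and controller configuration.
#' @param pump actuator (default a \linkS4class{MockPump}).
#' @param statsCsv,auditPath output artifacts.
#' @param pollInterval seconds between directory polls.
#' @param maxPolls stop after this many polls (Inf for a daemon).
#' @param channelMap,t0 passed to \code{\link{readFCS}}.
#' @param alpha,k,slopeOn trend parameters.
#' @param quarantineDir where malformed files are moved.
#' @param resume rebuild state from existing artifacts (default TRUE).
#' @param logFun function(level, msg, ...) for status logging.
#' @return List with \code{commands}, \code{state} (final
#'   \linkS4class{ControllerState}) and \code{processed} (paths), invisibly.
#' @export
runControl <- function(watchDir, gate = GateConfig(),
                       cfg = ControllerConfig(), pump = MockPump(),
                       statsCsv = file.path(watchDir, "stats.csv"),
                       auditPath = file.path(watchDir, "audit.jsonl"),
                       pollInterval = 60, maxPolls = Inf, channelMap = NULL,
                       t0 = NULL, alpha = 0.5, k = 3L, slopeOn = "ema",
                       quarantineDir = file.path(watchDir, "quarantine"),
                       resume = TRUE, logFun = .logLine) {
  state <- if (resume)
    resumeControllerState(statsCsv, auditPath, cfg, alpha, k, slopeOn)
  else ControllerState(alpha = alpha, k = k, slopeOn = slopeOn)

  seenFile <- paste0(statsCsv, ".seen")
  seen <- if (resume && file.exists(seenFile)) readLines(seenFile)
          else character(0)
  commands <- list()
  processed <- character(0)
  polls <- 0

  finishUp <- function() {
    ok <- tryCatch({actuate(pump, 0); TRUE},
                   cytoloop_actuator_error = function(e) {
                     logFun("alarm", "actuator unreachable at shutdown",
                            reason = conditionMessage(e))
                     FALSE
                   })
    tLast <- if (length(state@piTrend@times))
      max(state@piTrend@times) else 0
    writeAuditLog(list(list(t = tLast, sample_id = NA_character_,
                            mfi = NA_real_, mfi_ema = NA_real_,
                            mfi_slope = NA_real_, pct_pi = NA_real_,
                            pct_pi_ema = NA_real_, pi_slope = NA_real_,
                            pi_max = cfg@piMax, cause = "shutdown",
                            rate = 0)),
                  auditPath, append = TRUE)
    invisible(ok)
  }

  tryCatch({
    repeat {
      newFiles <- discoverNewSamples(watchDir, c(seen, processed), t0 = t0)
      newFiles <- newFiles[dirname(newFiles) != normalizePath(quarantineDir,
                                                              mustWork = FALSE)]
      for (pth in newFiles) {
        processed <- c(processed, pth)
        cat(pth, "\n", file = seenFile, append = TRUE, sep = "")
        tab <- tryCatch(readFCS(pth, channelMap = channelMap, t0 = t0),
                        cytoloop_error = function(e) {
                          if (!dir.exists(quarantineDir))
                            dir.create(quarantineDir, recursive = TRUE)
                          file.rename(pth, file.path(quarantineDir,
                                                     basename(pth)))
                          logFun("warn", "quarantined malformed FCS file",
                                 file = pth, reason = conditionMessage(e))
                          NULL
                        })
        if (is.null(tab)) next
        st <- summarizeSample(tab, classifyEvents(tab, gate), gate)
        if (st@usable) {
          res <- evaluateController(state, st, cfg)
          state <- res$state
          commands[[length(commands) + 1L]] <- res$command
          res$audit$time_source <- tab@timeSource
          writeAuditLog(list(res$audit), auditPath, append = TRUE)
          ok <- tryCatch({actuate(pump, res$command$rate); TRUE},
                         cytoloop_actuator_error = function(e) {
                           logFun("alarm", "actuator failure; pump assumed stopped",
                                  reason = conditionMessage(e))
                           FALSE
                         })
          if (!ok && res$command$rate > 0) {
            state@pumpOn <- FALSE   # conservative: treat the pump as stopped
          }
        } else {
          logFun("warn", "sample below minimum gated events; skipped",
                 sample = st@sampleId, gated = st@nTotal - st@nDebris)
          writeAuditLog(list(list(t = st@t, sample_id = st@sampleId,
                                  mfi = NA_real_, mfi_ema = NA_real_,
                                  mfi_slope = NA_real_, pct_pi = st@pctPi,
                                  pct_pi_ema = NA_real_, pi_slope = NA_real_,
                                  pi_max = cfg@piMax,
                                  cause = "skip_unusable", rate = NA_real_)),
                        auditPath, append = TRUE)
        }
        mfiEma <- if (length(state@mfiTrend@ema))
          state@mfiTrend@ema[length(state@mfiTrend@ema)] else NA_real_
        piEma <- if (length(state@piTrend@ema))
          state@piTrend@ema[length(state@piTrend@ema)] else NA_real_
        appendStatsCsv(st, statsCsv, mfiEma, piEma)
      }
      polls <- polls + 1
      if (polls >= maxPolls) break
      Sys.sleep(pollInterval)
    }
  }, interrupt = function(e) {
    logFun("info", "interrupt received; shutting down")
  })
  finishUp()
  cmds <- if (length(commands)) do.call(rbind, commands)
          else data.frame(t = numeric(0), rate = numeric(0),
                          cause = character(0), stringsAsFactors = FALSE)
  invisible(list(commands = cmds, state = state, processed = processed))
}

#' In-silico experiment front end
#'
#' Runs the fed-batch simulation in sensor-controlled or fixed-rate mode and
#' writes the trajectory CSV, statistics CSV, audit log and (optionally) the
#' synthesized FCS directory.
#'
#' @param p a \linkS4class{SimParams}; \code{seed} overrides its seed.
#' @param cfg,gate controller and gate configuration.
#' @param duration simulated feeding hours.
#' @param mode "controlled" or "fixed".
#' @param seed optional master seed override.
#' @param outDir optional FCS output directory.
#' @param trajectoryCsv,statsCsv,auditPath output artifacts (NULL to skip).
#' @param runId run identifier.
#' @param ... passed to \code{\link{runClosedLoop}}.
#' @return The \code{\link{runClosedLoop}} result, invisibly.
#' @export
runSimulate <- function(p = SimParams(), cfg = ControllerConfig(),
                        gate = GateConfig(), duration = 30,
                        mode = c("controlled", "fixed"), seed = NULL,
                        outDir = NULL, trajectoryCsv = NULL, statsCsv = NULL,
                        auditPath = NULL, runId = "sim", ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) p@seed <- as.integer(seed)
  res <- runClosedLoop(p, cfg, gate, duration = duration, mode = mode,
                       outDir = outDir, statsCsv = statsCsv,
                       auditPath = auditPath, runId = runId, ...)
  if (!is.null(trajectoryCsv))
    utils::write.csv(res$trajectory, trajectoryCsv, row.names = FALSE)
  invisible(res)
}
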