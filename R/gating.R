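#' Gate labels
#' @keywords internal
.gateLevels <- c("debris", "damaged", "intact_gfp_pos", "intact_gfp_neg")

#' Classify events by the two-step static gate
#'
#' Step one removes debris with a static forward-scatter threshold
#' (\code{FSC-H < fscMin}); step two classifies the remaining yeast events on
#' the PI axis (\code{FL3-H >= fl3Threshold} is "damaged", i.e. PI-stained)
#' and splits intact cells on the GFP axis (\code{FL1-H >= fl1Threshold} is
#' GFP-positive). Values exactly at a threshold go to the upper/positive
#' class. Every event gets exactly one label, so the four classes partition
#' the sample.
#'
#' @param table an \linkS4class{EventTable} containing FSC-H, FL1-H, FL3-H.
#' @param cfg a \linkS4class{GateConfig}.
#' @return A factor of per-event labels with levels
#'   \code{debris, damaged, intact_gfp_pos, intact_gfp_neg}.
#' @examples
#' m <- matrix(c(50,  900,  900,     # FSC-H
#'               10,   10,   10,     # SSC-H
#'               0,    10, 4000,     # FL1-H
#'               0,  5000,   10),    # FL3-H
#'             nrow = 3, dimnames = list(NULL, canonicalChannels))
#' cfg <- GateConfig(fscMin = 100, fl3Threshold = 1000, fl1Threshold = 500)
#' classifyEvents(EventTable(m), cfg)  # debris, damaged, intact_gfp_pos
#' @rdname classifyEvents
#' @export
setMethod("classifyEvents", signature("EventTable", "GateConfig"),
function(table, cfg) {
  need <- c("FSC-H", "FL1-H", "FL3-H")
  missing <- setdiff(need, channels(table))
  if (length(missing)) stopChannelError(missing[1])
  ev <- table@events
  lab <- ifelse(ev[, "FSC-H"] < cfg@fscMin, "debris",
         ifelse(ev[, "FL3-H"] >= cfg@fl3Threshold, "damaged",
         ifelse(ev[, "FL1-H"] >= cfg@fl1Threshold, "intact_gfp_pos",
                "intact_gfp_neg")))
  factor(lab, levels = .gateLevels)
})

#' Summarize a gated sample
#'
#' Computes the per-sample statistics the controller consumes: class counts,
#' the GFP mean fluorescence intensity (MFI) over the configured reference
#' population (by default all intact, PI-negative cells, since damaged cells
#' do not respond to the inducer), and the percentage of PI-stained cells
#' among gated (non-debris) events. The MFI is reported as undefined
#' (\code{NA}, flagged) rather than fabricated when the reference population
#' is empty. A sample is usable when at least \code{minEvents} gated events
#' were acquired.
#'
#' @param table an \linkS4class{EventTable}.
#' @param labels factor from \code{\link{classifyEvents}}; length must equal
#'   the event count.
#' @param cfg a \linkS4class{GateConfig}.
#' @return A \linkS4class{PopulationStats}.
#' @rdname summarizeSample
#' @export
setMethod("summarizeSample",
          signature("EventTable", "factor", "GateConfig"),
function(table, labels, cfg) {
  if (length(labels) != nEvents(table))
    stopConsistencyError(sprintf(
      "labels length (%d) does not match event count (%d)",
      length(labels), nEvents(table)))
  counts <- table(factor(labels, levels = .gateLevels))
  nTotal <- nEvents(table)
  nDebris <- as.integer(counts[["debris"]])
  nDamaged <- as.integer(counts[["damaged"]])
  nPos <- as.integer(counts[["intact_gfp_pos"]])
  nNeg <- as.integer(counts[["intact_gfp_neg"]])
  nGated <- nTotal - nDebris

  keep <- switch(cfg@mfiPopulation,
    intact = labels %in% c("intact_gfp_pos", "intact_gfp_neg"),
    all_gated = labels != "debris",
    gfp_pos = labels == "intact_gfp_pos")
  fl1 <- table@events[keep, "FL1-H"]
  mfiDefined <- length(fl1) > 0
  mfi <- if (!mfiDefined) NA_real_
         else if (cfg@mfiScale == "arithmetic") mean(fl1)
         else exp(mean(log(pmax(fl1, .Machine$double.xmin))))

  pctPi <- if (nGated > 0) 100 * nDamaged / nGated else NA_real_
  new("PopulationStats", sampleId = sampleId(table), t = acquiredAt(table),
      nTotal = as.integer(nTotal), nDebris = nDebris, nDamaged = nDamaged,
      nIntactGfpPos = nPos, nIntactGfpNeg = nNeg,
      mfiGfp = mfi, mfiDefined = mfiDefined, pctPi = pctPi,
      usable = nGated >= cfg@minEvents)
})

#' Construct PopulationStats directly
#'
#' Convenience constructor for controller tests and replaying persisted
#' statistics. When the class counts are not given they are synthesized
#' consistently with \code{pctPi} over 10000 gated events.
#'
#' @param t hours since feed start.
#' @param mfiGfp GFP MFI (NA for undefined).
#' @param pctPi percent PI-stained among gated events.
#' @param sampleId sample identifier.
#' @param usable usable flag (default TRUE).
#' @param nTotal,nDebris,nDamaged,nIntactGfpPos,nIntactGfpNeg optional exact
#'   counts; must partition nTotal.
#' @return A \linkS4class{PopulationStats}.
#' @export
PopulationStats <- function(t, mfiGfp, pctPi, sampleId = "sample",
                            usable = TRUE, nTotal = NULL, nDebris = 0L,
                            nDamaged = NULL, nIntactGfpPos = NULL,
                            nIntactGfpNeg = NULL) {
  if (is.null(nTotal)) {
    gated <- 10000L
    nDamaged <- as.integer(round(gated * pctPi / 100))
    nIntactGfpPos <- gated - nDamaged
    nIntactGfpNeg <- 0L
    nDebris <- 0L
    nTotal <- gated
  }
  new("PopulationStats", sampleId = as.character(sampleId), t = t,
      nTotal = as.integer(nTotal), nDebris = as.integer(nDebris),
      nDamaged = as.integer(nDamaged),
      nIntactGfpPos = as.integer(nIntactGfpPos),
      nIntactGfpNeg = as.integer(nIntactGfpNeg),
      mfiGfp = if (is.na(mfiGfp)) NA_real_ else mfiGfp,
      mfiDefined = !is.na(mfiGfp), pctPi = pctPi, usable = usable)
}

#' One-row data.frame view of per-sample statistics
#'
#' @param x a \linkS4class{PopulationStats}.
#' @param row.names,optional,... ignored (standard generic arguments).
#' @return A one-row \code{data.frame} matching the statistics CSV schema.
#' @export
as.data.frame.PopulationStats <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(sample_id = x@sampleId, t = x@t, n_total = x@nTotal,
             n_debris = x@nDebris, n_damaged = x@nDamaged,
             n_intact_gfp_pos = x@nIntactGfpPos,
             n_intact_gfp_neg = x@nIntactGfpNeg,
             mfi_gfp = x@mfiGfp, pct_pi = x@pctPi, usable = x@usable,
             stringsAsFactors = FALSE)
}

setMethod("sampleId", "PopulationStats", function(x) x@sampleId)

#' Append one sample's statistics (plus trend values) to the time-series CSV
#'
#' The statistics CSV is the run's monitoring artifact: one row per sample
#' with counts, MFI, percent PI, the usable flag and — once trend state
#' exists — the smoothed MFI and percent-PI values, persisted so a restarted
#' controller can resume the smoother exactly.
#'
#' @param stats a \linkS4class{PopulationStats}.
#' @param path CSV path; the header is written if the file does not exist.
#' @param mfiEma,piEma smoothed values at this sample (NA before smoothing).
#' @return The path, invisibly.
#' @export
appendStatsCsv <- function(stats, path, mfiEma = NA_real_, piEma = NA_real_) {
  row <- as.data.frame(stats)
  row$mfi_ema <- mfiEma
  row$pi_ema <- piEma
  newFile <- !file.exists(path)
  utils::write.table(row, path, sep = ",", append = !newFile,
                     col.names = newFile, row.names = FALSE, qmethod = "double")
  invisible(path)
}
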