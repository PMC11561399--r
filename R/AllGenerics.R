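#' @import methods
NULL

#' @rdname EventTable-class
#' @param object,x an object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname EventTable-class
#' @export
setGeneric("acquiredAt", function(x) standardGeneric("acquiredAt"))

#' @rdname EventTable-class
#' @export
setGeneric("dilutionFactor", function(x) standardGeneric("dilutionFactor"))

#' @rdname EventTable-class
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' @rdname EventTable-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname EventTable-class
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname classifyEvents
#' @export
setGeneric("classifyEvents", function(table, cfg) standardGeneric("classifyEvents"))

#' @rdname summarizeSample
#' @export
setGeneric("summarizeSample",
           function(table, labels, cfg) standardGeneric("summarizeSample"))

#' @rdname emaAppend
#' @export
setGeneric("emaAppend", function(series, t, x) standardGeneric("emaAppend"))

#' @rdname slopeLastK
#' @export
setGeneric("slopeLastK", function(series) standardGeneric("slopeLastK"))

#' @rdname evaluateController
#' @export
setGeneric("evaluateController",
           function(state, stats, cfg) standardGeneric("evaluateController"))

#' @rdname actuate
#' @export
setGeneric("actuate", function(pump, rate) standardGeneric("actuate"))

## ------------------------------------------------------------- accessors

#' @rdname EventTable-class
#' @export
setMethod("sampleId", "EventTable", function(x) x@sampleId)

#' @rdname EventTable-class
#' @export
setMethod("acquiredAt", "EventTable", function(x) x@acquiredAt)

#' @rdname EventTable-class
#' @export
setMethod("dilutionFactor", "EventTable", function(x) x@dilutionFactor)

#' @rdname EventTable-class
#' @export
setMethod("eventMatrix", "EventTable", function(x) x@events)

#' @rdname EventTable-class
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@events))

#' @rdname EventTable-class
#' @export
setMethod("channels", "EventTable", function(x) colnames(x@events))

## ----------------------------------------------------------------- show

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable '%s': %d events x %d channels (%s)\n",
              object@sampleId, nrow(object@events), ncol(object@events),
              paste(colnames(object@events), collapse = ", ")))
  cat(sprintf("  acquired at %.3f h (%s), dilution %gx\n",
              object@acquiredAt, object@timeSource, object@dilutionFactor))
})

setMethod("show", "PopulationStats", function(object) {
  cat(sprintf("PopulationStats '%s' @ %.2f h: %d events\n",
              object@sampleId, object@t, object@nTotal))
  cat(sprintf("  debris %d | damaged %d | intact GFP+ %d | intact GFP- %d\n",
              object@nDebris, object@nDamaged, object@nIntactGfpPos,
              object@nIntactGfpNeg))
  cat(sprintf("  MFI(GFP) %s | %%PI %s | usable %s\n",
              if (object@mfiDefined) sprintf("%.1f", object@mfiGfp) else "undefined",
              if (is.na(object@pctPi)) "undefined" else sprintf("%.2f", object@pctPi),
              object@usable))
})

setMethod("show", "TrendSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("TrendSeries: %d points, alpha = %g, k = %d, slope on %s\n",
              n, object@alpha, object@k, object@slopeOn))
  if (n > 0) {
    s <- slopeLastK(object)
    cat(sprintf("  last: t = %.2f h, raw = %.4g, ema = %.4g, slope = %s\n",
                object@times[n], object@raw[n], object@ema[n],
                if (is.na(s)) "undefined" else sprintf("%.4g /h", s)))
  }
})

setMethod("show", "ControllerState", function(object) {
  cat(sprintf("ControllerState: pump %s%s, %d usable sample(s) at current rate%s\n",
              if (object@pumpOn) "ON" else "off",
              if (object@ladderIndex > 0)
                sprintf(" (ladder position %d)", object@ladderIndex) else "",
              object@samplesAtRate,
              if (object@safeguardActive) ", SAFEGUARD ACTIVE" else ""))
})

setMethod("show", "SimState", function(object) {
  cat(sprintf(paste0("SimState @ %.2f h: V = %.3f L, X = %.2f g/L, ",
                     "Sg = %.2f, Sx = %.2f, Cf = %.3f g/L\n"),
              object@t, object@V, object@X, object@Sg, object@Sx, object@Cf))
  cat(sprintf("  adaptation %.3f | fluorescence %.1f | damaged %.1f%% | furfural fed %.0f mg\n",
              object@A, object@Fl, 100 * object@D, object@cumFurIn))
})
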