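#' Canonical detector names
#'
#' The four detectors the control loop relies on: forward/side scatter height
#' (particle size / granularity) and the two fluorescence heights used for the
#' GFP biosensor (FL1-H) and propidium iodide viability stain (FL3-H).
#'
#' @export
canonicalChannels <- c("FSC-H", "SSC-H", "FL1-H", "FL3-H")

## ---------------------------------------------------------------- EventTable

#' EventTable: per-event intensities for one cytometry sample
#'
#' Holds the listmode event matrix (one row per event, one column per
#' detector) together with the acquisition metadata the controller needs:
#' a sample identifier, the acquisition time expressed in decimal hours since
#' the start of the feeding phase, the dilution factor applied at sampling,
#' and which clock source the acquisition time came from.
#'
#' @slot sampleId character(1) sample identifier.
#' @slot acquiredAt numeric(1), hours since feed start.
#' @slot dilutionFactor numeric(1), e.g. 100 for a 100-fold dilution.
#' @slot events numeric matrix, non-negative finite intensities; column names
#'   are the (canonical) channel names.
#' @slot timeSource character(1), one of "keyword", "btim", "mtime",
#'   "supplied": where \code{acquiredAt} came from.
#'
#' @export
setClass("EventTable",
  representation(
    sampleId = "character",
    acquiredAt = "numeric",
    dilutionFactor = "numeric",
    events = "matrix",
    timeSource = "character"
  ),
  prototype(
    sampleId = "sample",
    acquiredAt = 0,
    dilutionFactor = 1,
    events = matrix(numeric(0), nrow = 0, ncol = 4,
                    dimnames = list(NULL, c("FSC-H", "SSC-H", "FL1-H", "FL3-H"))),
    timeSource = "supplied"
  )
)

setValidity("EventTable", function(object) {
  ev <- object@events
  if (!is.numeric(ev)) return("'events' must be a numeric matrix")
  if (is.null(colnames(ev)) || any(!nzchar(colnames(ev))))
    return("'events' must have non-empty column (channel) names")
  if (anyDuplicated(colnames(ev))) return("channel names must be unique")
  if (ncol(ev) < 1) return("at least one channel is required")
  if (length(ev) && (any(!is.finite(ev)) || any(ev < 0)))
    return("all intensities must be finite and non-negative")
  if (length(object@sampleId) != 1) return("'sampleId' must be length 1")
  if (length(object@acquiredAt) != 1 || !is.finite(object@acquiredAt))
    return("'acquiredAt' must be a finite scalar (hours)")
  if (length(object@dilutionFactor) != 1 || !is.finite(object@dilutionFactor) ||
      object@dilutionFactor <= 0)
    return("'dilutionFactor' must be a positive scalar")
  if (!object@timeSource %in% c("keyword", "btim", "mtime", "supplied"))
    return("'timeSource' must be one of keyword/btim/mtime/supplied")
  TRUE
})

#' Construct an EventTable
#'
#' @param events numeric matrix of intensities, one row per event; column
#'   names are channel names (at minimum the canonical four for gating).
#' @param sampleId sample identifier.
#' @param acquiredAt acquisition time, decimal hours since feed start.
#' @param dilutionFactor dilution applied at sampling (default 1).
#' @param timeSource provenance of \code{acquiredAt}.
#' @return An \linkS4class{EventTable}.
#' @examples
#' m <- matrix(c(5000, 2000, 100, 10), nrow = 1,
#'             dimnames = list(NULL, canonicalChannels))
#' EventTable(m, sampleId = "s1", acquiredAt = 0.5, dilutionFactor = 100)
#' @export
EventTable <- function(events, sampleId = "sample", acquiredAt = 0,
                       dilutionFactor = 1, timeSource = "supplied") {
  storage.mode(events) <- "double"
  new("EventTable", sampleId = as.character(sampleId),
      acquiredAt = as.numeric(acquiredAt),
      dilutionFactor = as.numeric(dilutionFactor),
      events = events, timeSource = timeSource)
}

## ---------------------------------------------------------------- GateConfig

#' GateConfig: static gating thresholds
#'
#' The two-step gate: a forward-scatter debris threshold followed by a
#' quadrant classification of the remaining yeast events on FL3-H (propidium
#' iodide; damaged vs intact) and FL1-H (GFP; positive vs negative).
#' Intensities exactly equal to a threshold fall in the upper/positive class.
#'
#' Default thresholds are calibrated once against the simulator's synthetic
#' populations (real instruments need run-specific values via the config
#' file; no universal numbers exist).
#'
#' @slot fscMin FSC-H debris threshold (events below are debris).
#' @slot fl3Threshold FL3-H boundary: at/above is PI-stained ("damaged").
#' @slot fl1Threshold FL1-H boundary: at/above is GFP-positive.
#' @slot minEvents minimum gated (non-debris) events for a usable sample.
#' @slot mfiPopulation which population the GFP MFI is computed over:
#'   "intact" (all PI-negative cells, default), "all_gated", or "gfp_pos".
#' @slot mfiScale "arithmetic" (default) or "geometric" mean.
#' @export
setClass("GateConfig",
  representation(fscMin = "numeric", fl3Threshold = "numeric",
                 fl1Threshold = "numeric", minEvents = "numeric",
                 mfiPopulation = "character", mfiScale = "character"),
  prototype(fscMin = 1000, fl3Threshold = 400, fl1Threshold = 250,
            minEvents = 100, mfiPopulation = "intact", mfiScale = "arithmetic")
)

setValidity("GateConfig", function(object) {
  for (s in c("fscMin", "fl3Threshold", "fl1Threshold", "minEvents")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a positive scalar", s))
  }
  if (object@minEvents < 1) return("'minEvents' must be >= 1")
  if (!object@mfiPopulation %in% c("intact", "all_gated", "gfp_pos"))
    return("'mfiPopulation' must be intact/all_gated/gfp_pos")
  if (!object@mfiScale %in% c("arithmetic", "geometric"))
    return("'mfiScale' must be arithmetic/geometric")
  TRUE
})

#' @rdname GateConfig-class
#' @param fscMin,fl3Threshold,fl1Threshold,minEvents,mfiPopulation,mfiScale
#'   see the class slots.
#' @return A \code{GateConfig}.
#' @export
GateConfig <- function(fscMin = 1000, fl3Threshold = 400, fl1Threshold = 250,
                       minEvents = 100, mfiPopulation = "intact",
                       mfiScale = "arithmetic") {
  new("GateConfig", fscMin = fscMin, fl3Threshold = fl3Threshold,
      fl1Threshold = fl1Threshold, minEvents = minEvents,
      mfiPopulation = mfiPopulation, mfiScale = mfiScale)
}

## ----------------------------------------------------------- PopulationStats

#' PopulationStats: per-sample gated summary
#'
#' Event counts per gate class (an exhaustive, disjoint partition of all
#' acquired events), the GFP mean fluorescence intensity among the configured
#' population, and the percentage of PI-stained cells among gated (non-debris)
#' events. \code{mfiGfp} is \code{NA} (with \code{mfiDefined = FALSE}) when
#' the reference population is empty; it is never fabricated.
#'
#' @slot sampleId sample identifier.
#' @slot t hours since feed start.
#' @slot nTotal,nDebris,nDamaged,nIntactGfpPos,nIntactGfpNeg class counts.
#' @slot mfiGfp GFP MFI (linear intensity scale) or NA.
#' @slot mfiDefined whether mfiGfp is defined.
#' @slot pctPi 100 * nDamaged / (nTotal - nDebris); NA when no gated events.
#' @slot usable whether nTotal - nDebris >= minEvents.
#' @export
setClass("PopulationStats",
  representation(sampleId = "character", t = "numeric",
                 nTotal = "integer", nDebris = "integer", nDamaged = "integer",
                 nIntactGfpPos = "integer", nIntactGfpNeg = "integer",
                 mfiGfp = "numeric", mfiDefined = "logical",
                 pctPi = "numeric", usable = "logical")
)

setValidity("PopulationStats", function(object) {
  n <- object@nDebris + object@nDamaged + object@nIntactGfpPos + object@nIntactGfpNeg
  if (!identical(n, object@nTotal))
    return("gate class counts must partition nTotal exactly")
  if (any(c(object@nTotal, object@nDebris, object@nDamaged,
            object@nIntactGfpPos, object@nIntactGfpNeg) < 0))
    return("counts must be non-negative")
  if (!is.na(object@pctPi) && (object@pctPi < 0 || object@pctPi > 100))
    return("pctPi must lie in [0, 100]")
  if (object@mfiDefined && (!is.finite(object@mfiGfp) || object@mfiGfp < 0))
    return("a defined mfiGfp must be finite and non-negative")
  TRUE
})

## ---------------------------------------------------------------- TrendSeries

#' TrendSeries: exponentially smoothed statistic with a slope window
#'
#' An append-only time series of one per-sample statistic together with its
#' exponential moving average (EMA), \code{ema[i] = alpha*raw[i] +
#' (1-alpha)*ema[i-1]} with \code{ema[1] = raw[1]}. The controller's trigger
#' is the ordinary least-squares slope of the last \code{k} smoothed values
#' against their acquisition times.
#'
#' @slot times hours, strictly increasing.
#' @slot raw raw statistic values.
#' @slot ema smoothed values, same length as raw.
#' @slot alpha smoothing weight in (0, 1]; default 0.5 (the span-3 convention
#'   alpha = 2/(k+1) for the three-point window).
#' @slot k slope window length in samples (default 3).
#' @slot slopeOn "ema" (default) or "raw": which series the slope is fit to.
#' @export
setClass("TrendSeries",
  representation(times = "numeric", raw = "numeric", ema = "numeric",
                 alpha = "numeric", k = "integer", slopeOn = "character"),
  prototype(times = numeric(0), raw = numeric(0), ema = numeric(0),
            alpha = 0.5, k = 3L, slopeOn = "ema")
)

setValidity("TrendSeries", function(object) {
  if (length(object@raw) != length(object@times) ||
      length(object@ema) != length(object@raw))
    return("'times', 'raw' and 'ema' must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("'times' must be strictly increasing")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha > 1)
    return("'alpha' must lie in (0, 1]")
  if (object@k < 2) return("'k' must be >= 2")
  if (!object@slopeOn %in% c("ema", "raw"))
    return("'slopeOn' must be 'ema' or 'raw'")
  TRUE
})

#' @rdname TrendSeries-class
#' @param alpha,k,slopeOn see the class slots.
#' @return An empty \code{TrendSeries}.
#' @export
TrendSeries <- function(alpha = 0.5, k = 3L, slopeOn = "ema") {
  new("TrendSeries", alpha = alpha, k = as.integer(k), slopeOn = slopeOn)
}

## ----------------------------------------------------------- ControllerConfig

#' ControllerConfig: feed-pump decision parameters
#'
#' The stepwise rate ladder for the secondary (concentrated furfural) pump,
#' the viability safeguard ceiling on smoothed percent PI-stained cells, and
#' the dwell rule (usable samples required at the current rate before an
#' escalation is considered).
#'
#' @slot rateLadder ordered pump rates in mL/hr; default c(1, 1.5, 3, 5).
#' @slot piMax safeguard ceiling on the smoothed percent of PI-stained cells;
#'   default 35 (percent).
#' @slot dwellSamples usable samples required at the current rate before
#'   escalation; default 3 (the slope window length).
#' @slot safeguardLatching if TRUE a safeguard stop latches the pump off for
#'   the rest of the run; default FALSE (pump may restart from the bottom of
#'   the ladder once the safeguard clears).
#' @slot piAverage "ema" (default): the safeguard ceiling tests the EMA of
#'   percent PI; "last_k_mean": plain mean of the last k raw values.
#' @export
setClass("ControllerConfig",
  representation(rateLadder = "numeric", piMax = "numeric",
                 dwellSamples = "integer", safeguardLatching = "logical",
                 piAverage = "character"),
  prototype(rateLadder = c(1, 1.5, 3, 5), piMax = 35, dwellSamples = 3L,
            safeguardLatching = FALSE, piAverage = "ema")
)

setValidity("ControllerConfig", function(object) {
  rl <- object@rateLadder
  if (length(rl) < 1 || any(!is.finite(rl)) || any(rl <= 0))
    return("'rateLadder' must be positive and non-empty")
  if (any(diff(rl) <= 0)) return("'rateLadder' must be strictly increasing")
  if (object@piMax <= 0 || object@piMax >= 100)
    return("'piMax' must lie in (0, 100)")
  if (object@dwellSamples < 1) return("'dwellSamples' must be >= 1")
  if (!object@piAverage %in% c("ema", "last_k_mean"))
    return("'piAverage' must be 'ema' or 'last_k_mean'")
  TRUE
})

#' @rdname ControllerConfig-class
#' @param rateLadder,piMax,dwellSamples,safeguardLatching,piAverage see slots.
#' @return A \code{ControllerConfig}.
#' @export
ControllerConfig <- function(rateLadder = c(1, 1.5, 3, 5), piMax = 35,
                             dwellSamples = 3L, safeguardLatching = FALSE,
                             piAverage = "ema") {
  new("ControllerConfig", rateLadder = rateLadder, piMax = piMax,
      dwellSamples = as.integer(dwellSamples),
      safeguardLatching = safeguardLatching, piAverage = piAverage)
}

## ----------------------------------------------------------- ControllerState

#' ControllerState: the pump state machine
#'
#' Tracks whether the secondary pump is on, its position on the rate ladder,
#' how many usable samples have been seen at the current rate, whether the
#' viability safeguard is active, and the smoothed MFI and percent-PI series
#' the decisions are computed from.
#'
#' @slot pumpOn logical.
#' @slot ladderIndex integer; 0 when the pump has never started, otherwise
#'   the 1-based position in the rate ladder.
#' @slot samplesAtRate usable samples evaluated since the last rate change.
#' @slot safeguardActive logical.
#' @slot mfiTrend,piTrend \linkS4class{TrendSeries} of GFP MFI and percent PI.
#' @export
setClass("ControllerState",
  representation(pumpOn = "logical", ladderIndex = "integer",
                 samplesAtRate = "integer", safeguardActive = "logical",
                 mfiTrend = "TrendSeries", piTrend = "TrendSeries"),
  prototype(pumpOn = FALSE, ladderIndex = 0L, samplesAtRate = 0L,
            safeguardActive = FALSE)
)

#' @rdname ControllerState-class
#' @param alpha,k EMA weight and slope window for both trend series.
#' @param slopeOn which series ("ema" or "raw") slopes are fit to.
#' @return A fresh \code{ControllerState} with the pump off.
#' @export
ControllerState <- function(alpha = 0.5, k = 3L, slopeOn = "ema") {
  new("ControllerState",
      mfiTrend = TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn),
      piTrend = TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn))
}

## ---------------------------------------------------------------- SimParams

#' SimParams: fed-batch simulator parameters
#'
#' Rate constants, feed composition, noise model and numerics for the
#' phenomenological closed-loop simulator. Feed composition and pump rates
#' follow the reference cultivation (primary feed 6.24 mL/hr carrying
#' 20 g/L glucose, 20 g/L xylose and 6.9 g/L furfural; secondary feed
#' 50 g/L furfural). The biosensor model is phenomenological: fluorescence is
#' induced in proportion to the effective stress signal
#' \code{s = Cf * (1 - A)} (furfural concentration discounted by the
#' population adaptation level A) and relaxes first-order toward the basal
#' level F0; membrane damage is driven by the same stress signal.
#'
#' @slot muMax max specific growth rate on glucose (1/h).
#' @slot KsGlc,KsXyl Monod constants (g/L).
#' @slot muXylFrac xylose growth rate as a fraction of muMax.
#' @slot Yxs biomass yield on sugar (g/g).
#' @slot glcSwitch glucose level (g/L) below which xylose uptake begins.
#' @slot qDetox specific furfural detoxification rate (g furfural/g CDW/h).
#' @slot Kf furfural saturation constant of detoxification (g/L).
#' @slot kInd fluorescence induction gain ((intensity/h) per (g/L stress)).
#' @slot kRelax fluorescence relaxation rate (1/h).
#' @slot F0 basal fluorescence (intensity units).
#' @slot kAdapt adaptation rate (1/h) while furfural is present.
#' @slot kDam damage induction rate ((fraction/h) per (g/L stress)).
#' @slot gammaDam adaptation exponent of the damage drive: damage responds to
#'   \code{Cf * (1 - A)^gammaDam}. With the default 2, adapted cells
#'   re-induce fluorescence without a renewed rise in membrane damage.
#' @slot kRec damage recovery rate (1/h).
#' @slot primaryRate primary feed rate (mL/hr), fixed at 6.24.
#' @slot feedGlc,feedXyl,feedFur primary feed composition (g/L): 20, 20, 6.9.
#' @slot secondaryFur secondary feed furfural concentration (g/L): 50.
#' @slot V0,X0,Sg0,Sx0 broth state at feed start (L, g CDW/L, g/L, g/L).
#' @slot cvFl1,cvFl3,cvFsc,cvSsc lognormal coefficients of variation of the
#'   synthesized per-event intensities.
#' @slot debrisFrac fraction of acquired events that are debris.
#' @slot eventsPerSample target events per synthesized sample.
#' @slot dilutionLadder allowed dilution factors (sorted).
#' @slot eventsPerProxyUnit predicted events at dilution 1 per unit of the
#'   cell-density proxy X*V (used by the adaptive dilution rule).
#' @slot dilutionBand upper band multiplier around the target event count.
#' @slot dt integration step (h) of the fixed-step RK4 solver.
#' @slot seed master RNG seed; per-sample synthesis uses derived substreams.
#' @export
setClass("SimParams",
  representation(
    muMax = "numeric", KsGlc = "numeric", KsXyl = "numeric",
    muXylFrac = "numeric", Yxs = "numeric", glcSwitch = "numeric",
    qDetox = "numeric", Kf = "numeric",
    kInd = "numeric", kRelax = "numeric", F0 = "numeric",
    kAdapt = "numeric", kDam = "numeric", gammaDam = "numeric",
    kRec = "numeric",
    primaryRate = "numeric", feedGlc = "numeric", feedXyl = "numeric",
    feedFur = "numeric", secondaryFur = "numeric",
    V0 = "numeric", X0 = "numeric", Sg0 = "numeric", Sx0 = "numeric",
    cvFl1 = "numeric", cvFl3 = "numeric", cvFsc = "numeric", cvSsc = "numeric",
    debrisFrac = "numeric", eventsPerSample = "integer",
    dilutionLadder = "numeric", eventsPerProxyUnit = "numeric",
    dilutionBand = "numeric", dt = "numeric", seed = "integer"
  ),
  prototype(
    muMax = 0.25, KsGlc = 0.5, KsXyl = 1.0, muXylFrac = 0.5, Yxs = 0.107,
    glcSwitch = 0.05,
    qDetox = 0.18, Kf = 0.2,
    kInd = 900, kRelax = 0.35, F0 = 100,
    kAdapt = 0.15, kDam = 2.6, gammaDam = 2, kRec = 0.12,
    primaryRate = 6.24, feedGlc = 20, feedXyl = 20, feedFur = 6.9,
    secondaryFur = 50,
    V0 = 0.2, X0 = 3, Sg0 = 0.1, Sx0 = 0.5,
    cvFl1 = 0.35, cvFl3 = 0.45, cvFsc = 0.25, cvSsc = 0.30,
    debrisFrac = 0.05, eventsPerSample = 5000L,
    dilutionLadder = c(10, 100, 1000), eventsPerProxyUnit = 6.7e5,
    dilutionBand = 1.5, dt = 0.01, seed = 1L
  )
)

setValidity("SimParams", function(object) {
  nonneg <- c("muMax", "KsGlc", "KsXyl", "muXylFrac", "Yxs", "glcSwitch",
              "qDetox", "Kf", "kInd", "kRelax", "F0", "kAdapt", "kDam",
              "gammaDam", "kRec", "primaryRate", "feedGlc", "feedXyl", "feedFur",
              "secondaryFur", "Sg0", "Sx0", "debrisFrac")
  for (s in nonneg) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      return(sprintf("'%s' must be a non-negative scalar", s))
  }
  if (object@dt <= 0) return("'dt' must be > 0")
  if (object@V0 <= 0 || object@X0 < 0) return("V0 must be > 0 and X0 >= 0")
  for (s in c("cvFl1", "cvFl3", "cvFsc", "cvSsc")) {
    if (slot(object, s) <= 0) return(sprintf("'%s' must be > 0", s))
  }
  if (object@debrisFrac >= 1) return("'debrisFrac' must be < 1")
  if (object@eventsPerSample < 1) return("'eventsPerSample' must be >= 1")
  if (length(object@dilutionLadder) < 1 || any(diff(object@dilutionLadder) <= 0))
    return("'dilutionLadder' must be non-empty and sorted ascending")
  TRUE
})

#' @rdname SimParams-class
#' @param ... named slot overrides of the defaults.
#' @return A \code{SimParams}.
#' @examples
#' SimParams(kAdapt = 0)   # a non-adapting population
#' @export
SimParams <- function(...) {
  args <- list(...)
  if ("eventsPerSample" %in% names(args))
    args$eventsPerSample <- as.integer(args$eventsPerSample)
  if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("SimParams"), args))
}

## ------------------------------------------------------------------ SimState

#' SimState: fed-batch broth state
#'
#' @slot t hours since feed start.
#' @slot V broth volume (L).
#' @slot X biomass (g CDW/L).
#' @slot Sg,Sx glucose, xylose (g/L).
#' @slot Cf furfural (g/L).
#' @slot A population adaptation level in [0, 1].
#' @slot Fl population-mean biosensor fluorescence (intensity units).
#' @slot D damaged-cell fraction in [0, 1].
#' @slot cumFurIn cumulative furfural fed since feed start (mg).
#' @slot cumFurDetox cumulative furfural detoxified (mg), for mass-balance
#'   checks.
#' @slot nClipped number of state components clipped to their invariant
#'   ranges so far (diagnostic).
#' @export
setClass("SimState",
  representation(t = "numeric", V = "numeric", X = "numeric",
                 Sg = "numeric", Sx = "numeric", Cf = "numeric",
                 A = "numeric", Fl = "numeric", D = "numeric",
                 cumFurIn = "numeric", cumFurDetox = "numeric",
                 nClipped = "integer"),
  prototype(t = 0, V = 0.2, X = 3, Sg = 0.1, Sx = 0.5, Cf = 0, A = 0,
            Fl = 100, D = 0, cumFurIn = 0, cumFurDetox = 0, nClipped = 0L)
)

setValidity("SimState", function(object) {
  if (object@V <= 0) return("'V' must be > 0")
  for (s in c("X", "Sg", "Sx", "Cf", "Fl", "cumFurIn", "cumFurDetox")) {
    if (slot(object, s) < 0) return(sprintf("'%s' must be >= 0", s))
  }
  if (object@A < 0 || object@A > 1) return("'A' must lie in [0, 1]")
  if (object@D < 0 || object@D > 1) return("'D' must lie in [0, 1]")
  TRUE
})

#' Initial broth state at feed start
#'
#' @param p a \linkS4class{SimParams}.
#' @return A \linkS4class{SimState} at t = 0 (start of feeding) with basal
#'   fluorescence, no furfural, no adaptation and no damage.
#' @export
initialSimState <- function(p = SimParams()) {
  new("SimState", t = 0, V = p@V0, X = p@X0, Sg = p@Sg0, Sx = p@Sx0,
      Cf = 0, A = 0, Fl = p@F0, D = 0, cumFurIn = 0, cumFurDetox = 0,
      nClipped = 0L)
}
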