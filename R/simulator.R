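## Phenomenological fed-batch simulator. The broth model tracks volume,
## biomass (Monod growth on glucose, then xylose after a diauxic switch),
## furfural (fed minus saturable biomass-specific detoxification minus
## dilution), a population adaptation level A in [0, 1], the population-mean
## biosensor fluorescence Fl (induced by the effective stress signal
## s = Cf * (1 - A), relaxing first-order to the basal level F0), and the
## damaged-cell fraction D (driven by Cf * (1 - A)^gammaDam, so adapted
## cells resist damage more strongly than they resist induction). Cumulative
## furfural fed and detoxified (mg) are integrated alongside for
## mass-balance checks.

.SIM_VARS <- c("V", "X", "Sg", "Sx", "Cf", "A", "Fl", "D",
               "cumFurIn", "cumFurDetox")

.stateVec <- function(state) {
  c(V = state@V, X = state@X, Sg = state@Sg, Sx = state@Sx, Cf = state@Cf,
    A = state@A, Fl = state@Fl, D = state@D,
    cumFurIn = state@cumFurIn, cumFurDetox = state@cumFurDetox)
}

#' Right-hand side of the broth model
#'
#' Exposed so the fixed-step integrator can be cross-checked against an
#' independent ODE solver.
#'
#' @param y named state vector (V, X, Sg, Sx, Cf, A, Fl, D, cumFurIn,
#'   cumFurDetox).
#' @param p a \linkS4class{SimParams}.
#' @param secondaryRate secondary pump rate (mL/hr).
#' @return Named vector of time derivatives.
#' @keywords internal
#' @export
simDerivs <- function(y, p, secondaryRate) {
  Fp <- p@primaryRate / 1000      # L/h
  Fs <- secondaryRate / 1000
  Fin <- Fp + Fs
  V <- y[["V"]]; X <- y[["X"]]; Sg <- y[["Sg"]]; Sx <- y[["Sx"]]
  Cf <- y[["Cf"]]; A <- y[["A"]]; Fl <- y[["Fl"]]; D <- y[["D"]]

  dil <- Fin / V
  muG <- p@muMax * Sg / (p@KsGlc + Sg)
  muX <- if (Sg < p@glcSwitch) {
    p@muMax * p@muXylFrac * Sx / (p@KsXyl + Sx)
  } else 0
  detox <- p@qDetox * X * Cf / (Cf + p@Kf)          # g/L/h
  s <- Cf * (1 - A)

  c(V = Fin,
    X = (muG + muX) * X - dil * X,
    Sg = Fp * p@feedGlc / V - dil * Sg - muG * X / p@Yxs,
    Sx = Fp * p@feedXyl / V - dil * Sx - muX * X / p@Yxs,
    Cf = (Fp * p@feedFur + Fs * p@secondaryFur) / V - dil * Cf - detox,
    A = p@kAdapt * as.numeric(Cf > 0) * (1 - A),
    Fl = p@kInd * s - p@kRelax * (Fl - p@F0),
    D = p@kDam * Cf * (1 - A)^p@gammaDam * (1 - D) - p@kRec * D,
    cumFurIn = p@primaryRate * p@feedFur + secondaryRate * p@secondaryFur,
    cumFurDetox = detox * V * 1000)                  # mg/h
}

#' Advance the broth state by one integration step
#'
#' One fixed-step 4th-order Runge-Kutta step of length \code{p@dt}. After
#' the step every state component is clipped to its invariant range
#' (concentrations >= 0, A and D in [0, 1]); clips beyond numerical noise
#' are counted in \code{nClipped}.
#'
#' @param state a \linkS4class{SimState}.
#' @param p a \linkS4class{SimParams}.
#' @param secondaryRate secondary pump rate in mL/hr (>= 0), held constant
#'   over the step.
#' @return The advanced \linkS4class{SimState}.
#' @export
simStep <- function(state, p, secondaryRate = 0) {
  if (secondaryRate < 0)
    stopValidationError("secondaryRate must be >= 0")
  h <- p@dt
  y <- .stateVec(state)
  k1 <- simDerivs(y, p, secondaryRate)
  k2 <- simDerivs(y + h / 2 * k1, p, secondaryRate)
  k3 <- simDerivs(y + h / 2 * k2, p, secondaryRate)
  k4 <- simDerivs(y + h * k3, p, secondaryRate)
  y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

  lo <- c(V = .Machine$double.eps, X = 0, Sg = 0, Sx = 0, Cf = 0, A = 0,
          Fl = 0, D = 0, cumFurIn = 0, cumFurDetox = 0)
  hi <- c(V = Inf, X = Inf, Sg = Inf, Sx = Inf, Cf = Inf, A = 1, Fl = Inf,
          D = 1, cumFurIn = Inf, cumFurDetox = Inf)
  clipped <- y < lo - 1e-9 | y > hi + 1e-9
  y <- pmin(pmax(y, lo), hi)

  new("SimState", t = state@t + h, V = y[["V"]], X = y[["X"]],
      Sg = y[["Sg"]], Sx = y[["Sx"]], Cf = y[["Cf"]], A = y[["A"]],
      Fl = y[["Fl"]], D = y[["D"]], cumFurIn = y[["cumFurIn"]],
      cumFurDetox = y[["cumFurDetox"]],
      nClipped = state@nClipped + as.integer(sum(clipped)))
}

#' Furfural mass balance of a simulated state
#'
#' Added minus detoxified minus in-broth furfural, which closes to zero up
#' to integration error (the in-broth term uses the initial inventory of the
#' reference state when supplied).
#'
#' @param state current \linkS4class{SimState}.
#' @param state0 state at the start of the balance window (default: zero
#'   initial furfural inventory).
#' @return List with \code{added}, \code{detoxified}, \code{inBroth} (all
#'   mg), \code{residual} and \code{relative} (residual / added).
#' @export
furfuralMassBalance <- function(state, state0 = NULL) {
  inv0 <- if (is.null(state0)) 0 else state0@Cf * state0@V * 1000
  added <- state@cumFurIn - (if (is.null(state0)) 0 else state0@cumFurIn)
  detox <- state@cumFurDetox - (if (is.null(state0)) 0 else state0@cumFurDetox)
  inBroth <- state@Cf * state@V * 1000 - inv0
  residual <- added - detox - inBroth
  list(added = added, detoxified = detox, inBroth = inBroth,
       residual = residual,
       relative = if (added > 0) residual / added else 0)
}

## Deterministic per-sample RNG substream derived from the master seed.
.substreamSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
             2147483647)
}

.withSubstream <- function(seed, index, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.substreamSeed(seed, index))
  force(expr)
}

.sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Choose a dilution factor from the adaptive-dilution ladder
#'
#' Emulates the at-line system's adaptive dilution policy: more dilution
#' steps at high cell density so the recorded events per sample stay
#' comparable across the cultivation. Returns the smallest ladder factor
#' whose predicted event count falls below \code{band * targetEvents}
#' (a count exactly at the band edge takes the next larger factor);
#' saturates at the ladder extremes.
#'
#' @param densityProxy cell-density proxy, biomass times volume (g CDW).
#' @param targetEvents desired events per sample.
#' @param ladder allowed dilution factors, sorted ascending.
#' @param eventsPerProxyUnit predicted events at dilution 1 per proxy unit.
#' @param band upper band multiplier (default 1.5).
#' @return One element of \code{ladder}.
#' @export
chooseDilution <- function(densityProxy, targetEvents,
                           ladder = c(10, 100, 1000),
                           eventsPerProxyUnit = 6.7e5, band = 1.5) {
  if (!length(ladder)) stopValidationError("dilution ladder must be non-empty")
  predicted <- eventsPerProxyUnit * densityProxy / ladder
  ok <- which(predicted < band * targetEvents)
  if (!length(ok)) ladder[length(ladder)] else ladder[min(ok)]
}

#' Synthesize one cytometry sample from the broth state
#'
#' Draws \code{eventsPerSample} events. A fraction \code{debrisFrac} is
#' low-scatter debris; the rest are yeast, split damaged (fraction \code{D})
#' versus intact. Per-event intensities are lognormal around class medians:
#' intact cells' FL1-H median follows the population fluorescence \code{Fl}
#' while damaged cells' FL1-H stays near the basal level (damaged cells do
#' not respond to the inducer); FL3-H (propidium iodide) is high for damaged
#' and low for intact cells. The dilution factor is chosen by
#' \code{\link{chooseDilution}} and recorded in the sample metadata.
#' Synthesis is reproducible: the RNG substream is derived from the master
#' seed and \code{sampleIndex} only.
#'
#' @param state a \linkS4class{SimState}.
#' @param p a \linkS4class{SimParams}.
#' @param sampleIndex 1-based index of this sample in the run (selects the
#'   RNG substream).
#' @param runId sample-id prefix.
#' @return An \linkS4class{EventTable} with the canonical four channels.
#' @export
synthesizeSample <- function(state, p, sampleIndex = 1L, runId = "sim") {
  n <- p@eventsPerSample
  .withSubstream(p@seed, sampleIndex, {
    counts <- stats::rmultinom(1, n, c(
      debris = p@debrisFrac,
      damaged = (1 - p@debrisFrac) * state@D,
      intact = (1 - p@debrisFrac) * (1 - state@D)))[, 1]
    med <- list(
      debris = c(fsc = 200, ssc = 100, fl1 = 5, fl3 = 5),
      damaged = c(fsc = 5000, ssc = 2000, fl1 = p@F0, fl3 = 4000),
      intact = c(fsc = 5000, ssc = 2000, fl1 = max(state@Fl, 1e-6), fl3 = 40))
    draw <- function(cls, nc) {
      m <- med[[cls]]
      cbind(stats::rlnorm(nc, log(m[["fsc"]]), .sdlog(p@cvFsc)),
            stats::rlnorm(nc, log(m[["ssc"]]), .sdlog(p@cvSsc)),
            stats::rlnorm(nc, log(m[["fl1"]]), .sdlog(p@cvFl1)),
            stats::rlnorm(nc, log(m[["fl3"]]), .sdlog(p@cvFl3)))
    }
    ev <- do.call(rbind, lapply(names(counts)[counts > 0],
                                function(cls) draw(cls, counts[[cls]])))
    if (is.null(ev)) ev <- matrix(numeric(0), nrow = 0, ncol = 4)
    if (nrow(ev) > 1) ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    colnames(ev) <- canonicalChannels
    EventTable(ev,
               sampleId = sprintf("%s_t%05.1f", runId, state@t),
               acquiredAt = state@t,
               dilutionFactor = chooseDilution(
                 state@X * state@V, p@eventsPerSample, p@dilutionLadder,
                 p@eventsPerProxyUnit, p@dilutionBand),
               timeSource = "supplied")
  })
}

#' Run the closed-loop (or fixed-rate) in-silico cultivation
#'
#' Simulates the feeding phase: every \code{samplingInterval} hours a
#' cytometry sample is synthesized from the broth state, gated and
#' summarized, the trend series are updated, and — in \code{"controlled"}
#' mode — the pump state machine sets the secondary feed rate applied to the
#' subsequent integration steps. In \code{"fixed"} mode the secondary rate
#' is pinned to 0, reproducing the fixed-feed-rate reference arm. A furfural
#' mass-balance integrity check runs at every sample.
#'
#' @param p a \linkS4class{SimParams}.
#' @param cfg a \linkS4class{ControllerConfig} (controlled mode).
#' @param gate a \linkS4class{GateConfig}.
#' @param duration simulated feeding time, hours.
#' @param mode \code{"controlled"} (sensor-controlled secondary feed) or
#'   \code{"fixed"} (secondary pump off throughout).
#' @param samplingInterval hours between samples (default 0.5, the at-line
#'   cadence).
#' @param outDir optional directory: synthesized samples are also written as
#'   FCS files (\code{<runId>_t<hours>.fcs}), consumed identically to real
#'   acquisitions.
#' @param statsCsv optional path for the per-sample statistics CSV.
#' @param auditPath optional path for the JSON-lines audit log.
#' @param runId run identifier used in sample ids and file names.
#' @param alpha,k,slopeOn trend parameters.
#' @param pump optional actuator receiving every commanded rate.
#' @param stateHook optional \code{function(state, t)} returning a possibly
#'   modified \linkS4class{SimState}, applied just before each sample is
#'   drawn (used to inject disturbances).
#' @param balanceTol runtime mass-balance tolerance (relative; integrity
#'   error beyond it).
#' @return A list: \code{trajectory} (data.frame, one row per sample:
#'   broth state, commanded rate), \code{stats} (per-sample statistics
#'   data.frame with EMA columns), \code{commands}, \code{audit},
#'   \code{state} (final \code{SimState}), \code{controller} (final
#'   \code{ControllerState} or NULL), \code{files} (FCS paths or NULL).
#' @export
runClosedLoop <- function(p = SimParams(), cfg = ControllerConfig(),
                          gate = GateConfig(), duration = 30,
                          mode = c("controlled", "fixed"),
                          samplingInterval = 0.5, outDir = NULL,
                          statsCsv = NULL, auditPath = NULL, runId = "sim",
                          alpha = 0.5, k = 3L, slopeOn = "ema", pump = NULL,
                          stateHook = NULL, balanceTol = 0.02) {
  mode <- match.arg(mode)
  if (duration <= 0) stopValidationError("'duration' must be > 0")
  nSamples <- floor(duration / samplingInterval)
  stepsPerSample <- round(samplingInterval / p@dt)
  if (abs(stepsPerSample * p@dt - samplingInterval) > 1e-9)
    stopValidationError("samplingInterval must be a multiple of dt")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if (!is.null(statsCsv) && file.exists(statsCsv)) unlink(statsCsv)
  if (!is.null(auditPath) && file.exists(auditPath)) unlink(auditPath)

  state <- initialSimState(p)
  ctrl <- if (mode == "controlled")
    ControllerState(alpha = alpha, k = k, slopeOn = slopeOn) else NULL
  ## fixed-rate runs are monitored (smoothed) without actuation
  mfiTrendF <- TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn)
  piTrendF <- TrendSeries(alpha = alpha, k = k, slopeOn = slopeOn)
  rate <- 0
  traj <- vector("list", nSamples)
  statsRows <- vector("list", nSamples)
  audit <- list()
  commands <- list()
  files <- if (!is.null(outDir)) character(nSamples) else NULL

  for (i in seq_len(nSamples)) {
    for (j in seq_len(stepsPerSample)) state <- simStep(state, p, rate)
    if (!is.null(stateHook)) state <- stateHook(state, state@t)

    mb <- furfuralMassBalance(state)
    if (mb$added > 1 && abs(mb$relative) > balanceTol)
      stopIntegrityError(sprintf(
        "furfural mass balance residual %.2f%% exceeds %.2f%% at t = %.2f h",
        100 * abs(mb$relative), 100 * balanceTol, state@t))

    tab <- synthesizeSample(state, p, sampleIndex = i, runId = runId)
    if (!is.null(outDir)) {
      f <- file.path(outDir, sprintf("%s_t%05.1f.fcs", runId, state@t))
      writeFCS(tab, f)
      tab <- readFCS(f)       # consume through the same interface as a real file
      files[i] <- f
    }
    labels <- classifyEvents(tab, gate)
    st <- summarizeSample(tab, labels, gate)

    if (mode == "controlled") {
      if (st@usable) {
        res <- evaluateController(ctrl, st, cfg)
        ctrl <- res$state
        rate <- res$command$rate
        commands[[length(commands) + 1L]] <- res$command
        audit[[length(audit) + 1L]] <- res$audit
        if (!is.null(pump)) actuate(pump, rate)
      } else {
        audit[[length(audit) + 1L]] <-
          list(t = st@t, sample_id = st@sampleId, mfi = NA_real_,
               mfi_ema = NA_real_, mfi_slope = NA_real_, pct_pi = st@pctPi,
               pct_pi_ema = NA_real_, pi_slope = NA_real_, pi_max = cfg@piMax,
               cause = "skip_unusable", rate = NA_real_)
      }
    }

    if (mode == "fixed") {
      if (st@mfiDefined) mfiTrendF <- emaAppend(mfiTrendF, st@t, st@mfiGfp)
      if (!is.na(st@pctPi)) piTrendF <- emaAppend(piTrendF, st@t, st@pctPi)
    }
    mfiT <- if (mode == "controlled") ctrl@mfiTrend else mfiTrendF
    piT <- if (mode == "controlled") ctrl@piTrend else piTrendF
    mfiEma <- if (length(mfiT@ema)) mfiT@ema[length(mfiT@ema)] else NA_real_
    piEma <- if (length(piT@ema)) piT@ema[length(piT@ema)] else NA_real_
    row <- as.data.frame(st)
    row$mfi_ema <- mfiEma
    row$pi_ema <- piEma
    statsRows[[i]] <- row
    if (!is.null(statsCsv)) appendStatsCsv(st, statsCsv, mfiEma, piEma)

    traj[[i]] <- data.frame(
      t = state@t, V = state@V, X = state@X, Sg = state@Sg, Sx = state@Sx,
      Cf = state@Cf, A = state@A, Fl = state@Fl, D = state@D,
      cum_fur_in = state@cumFurIn, cum_fur_detox = state@cumFurDetox,
      secondary_rate = rate)
  }
  if (!is.null(auditPath) && length(audit)) writeAuditLog(audit, auditPath)

  cmds <- if (length(commands)) do.call(rbind, commands)
          else data.frame(t = numeric(0), rate = numeric(0),
                          cause = character(0), stringsAsFactors = FALSE)
  list(trajectory = do.call(rbind, traj),
       stats = do.call(rbind, statsRows),
       commands = cmds, audit = audit, state = state, controller = ctrl,
       files = files)
}
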