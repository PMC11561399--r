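---
title: "Reactive flow-cytometry control of fed-batch feeding: methods and design"
author: "cytoloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive flow-cytometry control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoloop)
```

## The control problem

Lignocellulosic hydrolysates contain furfural, an inhibitor that drains
NADPH as yeast reduces it to furfuryl alcohol. A *TRX2*p-*yEGFP*
transcription-factor biosensor reports this redox imbalance as GFP
fluorescence, measurable per cell by at-line flow cytometry. During a
fed-batch cultivation the biosensor output first rises (induction), then
falls as the population adapts and detoxifies faster than furfural arrives.
That decline is an actionable signal: the culture can tolerate more
inhibitor. cytoloop implements the corresponding feedback loop:

1. every 30 minutes a flow-cytometry sample (FCS file) arrives;
2. events are gated into debris / damaged / intact-GFP-positive /
   intact-GFP-negative subpopulations;
3. the GFP mean fluorescence intensity (MFI) of intact cells and the
   percentage of propidium-iodide (PI) stained cells are smoothed with an
   exponential moving average (EMA);
4. when the three-point slope of the smoothed MFI turns negative, a
   secondary pump feeding concentrated furfural (50 g/L) starts at 1 mL/hr
   and escalates stepwise through 1.5, 3 and 5 mL/hr on subsequent declines;
5. a viability safeguard stops the pump whenever the PI trend rises or the
   smoothed percent-PI exceeds 35%.

The primary feed (rich medium with 20 g/L glucose, 20 g/L xylose and
6.9 g/L furfural at a fixed 6.24 mL/hr) is outside the loop. All times are
decimal hours with zero at the start of the feeding phase.

Because the wet-lab system (strain, cytometer, pumps) is not reproducible
from software, the package pairs the controller with a closed-loop
fed-batch simulator that synthesizes event-level FCS files, so that every
layer — file parsing through pump actuation — runs and is tested end to end.

## Gating

Gating is deliberately static, matching at-line practice where thresholds
are fixed once per run:

* debris: `FSC-H < fscMin`;
* damaged: remaining events with `FL3-H >= fl3Threshold` (PI-stained);
* intact GFP-positive / negative: split at `FL1-H >= fl1Threshold`.

Ties go to the upper/positive class, so the rule is deterministic and the
four classes partition every sample exactly. Three choices are configurable
because the field does not fix them:

* **MFI population** (`mfiPopulation`, default `"intact"`): damaged cells do
  not respond to the inducer, so including them dilutes the control signal;
  the MFI is therefore computed over all PI-negative cells by default, with
  `"all_gated"` and `"gfp_pos"` as alternatives.
* **MFI scale** (`mfiScale`, default arithmetic on the linear intensity
  scale; geometric available).
* **percent PI denominator**: gated (non-debris) events, since debris is
  removed from all calculations.

The default thresholds (fscMin 1000, fl3Threshold 400, fl1Threshold 250)
were calibrated once against the simulator's synthetic populations, whose
class medians are separated by more than five lognormal standard deviations
from each boundary. Real instruments need run-specific values via the
configuration file. A sample is *usable* when at least `minEvents` (default
100) gated events were acquired; unusable samples are logged and skipped by
the trend and controller layers, never silently dropped.

## Trend estimation

Each statistic is smoothed recursively, `ema[i] = alpha*raw[i] +
(1-alpha)*ema[i-1]`, with the first value passing through. The default
`alpha = 0.5` is the span-matched weight `2/(k+1)` for the three-point
window `k = 3`; both are configuration knobs because the original
implementation's weight is not recoverable. The trigger signal is the
ordinary least-squares slope of the last three *smoothed* values against
their actual acquisition times — fitting the smoothed series is the most
literal composition of "smooth to suppress outliers, then take the slope",
and regressing on real times handles skipped samples naturally. A slope is
undefined (and triggers nothing) until three points exist. Fitting the raw
series instead is available via `slopeOn = "raw"`.

## The pump state machine

`evaluateController()` applies four rules in strict priority order:

1. **Safeguard**: PI slope > 0 *or* smoothed percent-PI > 35% commands
   rate 0, regardless of everything else. "Average number of PI-stained
   cells" is read as the EMA of percent-PI (the already-defined smoother;
   a plain last-k mean is available via `piAverage`).
2. **Start**: pump off, safeguard clear, MFI slope defined and strictly
   negative starts the pump at 1 mL/hr.
3. **Escalate**: pump on, safeguard clear, at least `dwellSamples` (default
   3, the slope window) usable samples at the current rate, and a negative
   MFI slope move the rate up exactly one ladder position. The dwell rule is
   an anti-chatter addition: judging "a decrease at the previous flow rate"
   requires at least a full slope window of samples at that rate.
4. **Hold** otherwise.

A slope of exactly zero is non-negative ("negative" is strict). The top
rate is absorbing except for safeguard stops. The safeguard is non-latching
by default: once PI conditions clear and the MFI declines again, the pump
restarts — conservatively from the bottom of the ladder, not the pre-stop
rate, since the source system never described a restart; a latching mode is
provided. Every evaluation appends one audit record (time, smoothed values,
slopes, thresholds, cause, commanded rate) to a JSON-lines log; the log is
deterministic given the statistics stream and replays to the exact command
sequence.

Actuation is a pluggable contract: a mock pump that records commands, and a
serial-line pump speaking `RATE <ml_per_hr>\n` / `OK\n` over any R
connection, with one retry and then an alarm (callers then assume the pump
stopped).

## The simulator

The broth model is phenomenological; rate equations were chosen to
reproduce the qualitative trajectory shapes the control strategy exploits,
not to be mechanistically predictive. State variables: volume `V`, biomass
`X`, glucose `Sg`, xylose `Sx` (Monod growth, diauxic switch below
`glcSwitch`), furfural `Cf`, adaptation `A` in [0, 1], population-mean
fluorescence `Fl`, damaged fraction `D`, plus cumulative furfural fed and
detoxified for mass-balance checks. The key equations:

* furfural: `dCf/dt = inflow/V - dilution - qDetox * X * Cf / (Cf + Kf)`;
* adaptation: `dA/dt = kAdapt * 1[Cf > 0] * (1 - A)`;
* effective stress: `s = Cf * (1 - A)`;
* fluorescence: `dFl/dt = kInd * s - kRelax * (Fl - F0)`;
* damage: `dD/dt = kDam * Cf * (1 - A)^gammaDam * (1 - D) - kRec * D`.

Two design points deserve justification:

* **Saturable detoxification near its operating point.** `qDetox` and `Kf`
  place the default fixed-feed steady state well inside the population's
  detoxification capacity (no accumulation, as observed in the reference
  arm), but close enough to saturation that the secondary feed produces a
  several-fold furfural rise — the steep response that makes re-induction
  visible above measurement noise.
* **Damage adapts more steeply than induction** (`gammaDam = 2`). If damage
  tracked the same stress signal as fluorescence, every re-induction would
  also raise percent-PI and trip the safeguard. Observed behavior is the
  opposite: once adapted, cultures absorb substantially more furfural with
  *no* rise in PI staining while still re-inducing the biosensor. Squaring
  the `(1 - A)` factor in the damage drive encodes exactly that asymmetry.

Default rate constants were tuned once against the qualitative template of
the reference cultivation — fixed-rate arm: a single fluorescence peak
between 3 and 8 h returning to the basal level, percent-PI peaking at
30–40% a few hours into feeding and declining toward ~10%; sensor-controlled
arm: pump start shortly after the induction peak, a clear second induction
peak, stepwise escalation to 5 mL/hr — and are not revisited. Absolute
intensities, the fold-increase in furfural fed, and timing details depend on
these invented constants and are deliberately not treated as quantitative
claims about the wet-lab system.

### Numerics

Integration is classical fixed-step RK4 (`dt = 0.01` h), chosen over an
adaptive solver for bit-level reproducibility and zero solver dependence;
the model is non-stiff at these scales. After each step states are clipped
to their invariant ranges (clips are counted). On smooth parameter sets the
integrator shows its nominal fourth-order convergence; the diauxic
indicator and the `Cf > 0` adaptation gate introduce isolated kinks that
locally reduce the order without affecting the trajectories' fidelity (the
test suite cross-checks a trajectory against an adaptive reference solver).
The furfural mass balance (fed − detoxified − in broth) is asserted at
every sampling instant and closes to well under 0.5% at the default step.

### Event synthesis

Each sample draws `eventsPerSample` (default 5000, matching at-line event
yields) class memberships from a multinomial: `debrisFrac` debris, the rest
damaged with probability `D` versus intact. Intensities are lognormal
around class medians; the intact FL1-H median follows `Fl`, damaged cells'
FL1-H stays at the basal level (they do not respond to the inducer), FL3-H
is high only for damaged cells. Coefficients of variation (0.25–0.45) are
typical of yeast cytometry. The dilution factor is chosen by the adaptive
rule — smallest ladder factor keeping the predicted event count below 1.5×
the target, emulating at-line systems that dilute more at high cell density
— and is recorded in a custom FCS keyword. Randomness derives from one
master seed fanned out into a deterministic substream per sample index, so
any single sample is reproducible in isolation.

What the generator does *not* emulate: instrument drift, spectral spillover,
doublets, clogging artifacts, skewed or multi-modal subpopulation structure,
and biological noise in the broth dynamics (the ODE trajectory is
deterministic). Passing closed-loop tests therefore demonstrate the
correctness and robustness of the decision logic against sampling noise,
not performance on real acquisitions.

## FCS dialect

Files are written as FCS 3.1, single dataset, listmode, 32-bit IEEE floats,
little-endian — a minimal, widely readable dialect. Reading additionally
accepts FCS 3.0, big-endian byte orders, and linear-scaled integer data
(16/32-bit), which covers common bench-top exports; log-amplified integer
data, multi-dataset files and analysis segments are out of scope and
rejected with typed errors. Acquisition-time precedence is: exact
decimal-hour custom keyword (`CYTOLOOP$ACQHOURS`), then `$BTIM`/`$DATE`,
then file modification time; the source used is recorded per sample and in
the audit log, because slope estimation needs a consistent clock.
Detector-label mapping to the canonical FSC-H/SSC-H/FL1-H/FL3-H names lives
in configuration.

## Problem sizes and test design

The in-silico experiments run a 30 h feeding phase at 30-minute sampling
(60 samples) with 5000 events per sample — a scale chosen so a full
two-arm comparison completes in seconds while keeping per-sample MFI
standard errors below 1% of signal. Property-style suites use 10⁴-event
samples for gating fuzz, 100 random tables for oracle equivalence, and 10⁴
random statistic streams for controller safety fuzzing. The
adaptation-dichotomy test isolates the trigger mechanism with furfural
supplied beyond detoxification capacity (`qDetox = 0.05`) and the damage
channel disabled (`kDam = 0`): without adaptation the smoothed MFI keeps
rising and the pump must never start; with adaptation it declines and the
pump must start — on ten seeds each.

## Known limitations

* The biosensor and damage models are invented phenomenology; constants are
  calibrated to trajectory *shapes*, so fold-changes and absolute
  intensities are not comparable to wet-lab values.
* Quadrant thresholds are static; density-based auto-gating, doublet
  discrimination and compensation are out of scope.
* The controller never de-escalates below the current rate except by
  stopping entirely (safeguard); whether the original system could lower
  rates is unknown, and the conservative reading was chosen.
* Late in a plateau, PI-slope noise can cause sporadic safeguard stops
  followed by bottom-of-ladder restarts; this is the honest behavior of the
  published rule under sampling noise, visible in long simulated runs.
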