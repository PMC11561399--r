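# cytoloop

Reactive flow-cytometry feedback control for fed-batch yeast cultivation.

## The problem

Furfural, a major inhibitor in lignocellulosic hydrolysates, drains NADPH
as *Saccharomyces cerevisiae* reduces it to furfuryl alcohol. A
*TRX2*p-*yEGFP* biosensor reports the resulting redox imbalance as
per-cell GFP fluorescence, measurable every 30 minutes by at-line flow
cytometry. During feeding the biosensor first induces, then declines as the
population adapts — a signal that the culture can tolerate more inhibitor.
cytoloop turns that signal into a control loop for people running (or
studying) biosensor-driven bioprocesses:

- **FCS I/O** — reads and writes a well-defined FCS 3.1 listmode subset, so
  the controller consumes real cytometer drops and the simulator produces
  byte-compatible files.
- **Gating** — static forward-scatter debris gate, then quadrant
  classification on PI (FL3-H) and GFP (FL1-H) into damaged /
  intact-GFP-positive / intact-GFP-negative; per-sample statistics (GFP MFI
  of intact cells, % PI-stained).
- **Trend** — exponential moving average (default `alpha = 0.5`) and the
  ordinary least-squares slope of the last three smoothed points.
- **Controller** — the feed state machine: when the MFI slope turns
  negative, start a secondary feed of 50 g/L furfural at 1 mL/hr and
  escalate stepwise through 1.5, 3, 5 mL/hr on subsequent declines; stop
  whenever the PI trend rises or smoothed %PI exceeds 35%
  (`rate ∈ {0} ∪ {1, 1.5, 3, 5}`, one step per decision, audit-logged).
- **Simulator** — closed-loop fed-batch model (Monod growth, saturable
  furfural detoxification, adaptation-discounted biosensor induction
  `dFl/dt = k_ind·Cf·(1−A) − k_relax·(Fl−F0)`, membrane-damage dynamics)
  with event-level lognormal FCS synthesis, so the whole chain runs without
  hardware.

## Worked example

Simulate both feeding arms of a 30 h feeding phase (60 samples at the
30-minute cadence) and inspect the controller's decisions:

```r
library(cytoloop)
p <- SimParams(seed = 42)

ffr  <- runClosedLoop(p, duration = 30, mode = "fixed")       # reference arm
scfr <- runClosedLoop(p, duration = 30, mode = "controlled")  # sensor-controlled

cmd <- scfr$commands
cmd[cmd$cause %in% c("induction_decline_start", "escalate"), ]
#>   t rate                   cause
#>   7  1.0 induction_decline_start
#>  11  1.0 induction_decline_start
#>  13  1.5                escalate
#>  15  3.0                escalate
#>  21  5.0                escalate
```

The fixed-rate arm shows the single induction transient; the controlled arm
starts the furfural pump once the smoothed MFI declines (7 h here), produces
a second induction peak, then walks the rate ladder:

```r
max(ffr$stats$mfi_gfp)                 # 245  (basal F0 = 100)
tail(ffr$stats$mfi_ema, 1)             # 109  — re-adapted by 30 h
tail(ffr$trajectory$cum_fur_in, 1)     # 1292 mg furfural fed
tail(scfr$trajectory$cum_fur_in, 1)    # 4842 mg — 3.7-fold more, at rate 5 mL/hr
```

(The early `safeguard_stop` records with the pump already off are the
viability guard holding the start back while %PI transits its initial
30–40% peak.) Offline analysis of any FCS directory and a live polling
controller use the same components:

```r
runAnalyze("path/to/fcs", statsCsv = "stats.csv")     # Fig-4-style time series
runControl("path/to/fcs", pump = MockPump(), maxPolls = 1, pollInterval = 0)
```

A command-line front end (`inst/cli/cytoloop.R`) wraps the three workflows
(`control`, `analyze`, `simulate`) over a plain-text config file; see
`inst/extdata/example.cfg`.

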