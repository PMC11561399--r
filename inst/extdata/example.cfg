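# Example run configuration.
# Values omitted here fall back to the package defaults.

[run]
mode = simulate
poll_interval = 60          ; seconds between directory polls (control mode)
log_level = info

[paths]
watch_dir = ./fcs_in
out_dir = ./fcs_out
stats_csv = ./stats.csv
audit_log = ./audit.jsonl

[gate]
fsc_min = 1000
fl3_threshold = 400
fl1_threshold = 250
min_events = 100
mfi_population = intact     ; intact | all_gated | gfp_pos

[trend]
alpha = 0.5                 ; EMA weight; 0.5 is the span-3 convention
k = 3                       ; slope window, samples
slope_on = ema              ; ema | raw

[controller]
rate_ladder = 1, 1.5, 3, 5  ; mL/hr
pi_max = 35                 ; percent PI-stained safeguard ceiling
dwell_samples = 3
safeguard_latching = false
pi_average = ema            ; ema | last_k_mean

[sim]
seed = 1
dt = 0.01                   ; h
events_per_sample = 5000
primary_rate = 6.24         ; mL/hr
feed_glc = 20               ; g/L
feed_xyl = 20
feed_fur = 6.9
secondary_fur = 50

[actuator]
type = mock                 ; mock | serial
port =
timeout = 2

[channels]
; instrument detector label -> canonical name, e.g.:
; BL1-H = FL1-H
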