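# photopeth

Fiber-photometry denoising by sequential regression, with peri-event
analysis of operant and consummatory behavior.

## What problem this solves

Dual-wavelength fiber photometry records a calcium-dependent fluorescence
channel (473 nm excitation of GCaMP) multiplexed frame-by-frame with an
isosbestic reference channel (405 nm, calcium-independent), plus a second
fiber in a dye tube that sees only laser power. The raw signal mixes the
calcium transients of interest with camera background, photobleaching,
laser-power drift, and motion artifacts. `photopeth` implements the
two-stage-regression processing chain that separates them, and the
surrounding analyses used in operant neurophysiology experiments: trial
parsing of fixed-ratio lever-press sessions, peri-event time histograms,
lick-bout microstructure, movement/approach detection from open-field
trajectories, intrinsic-property extraction from current-clamp sweeps, and
area-corrected tract-tracing count ratios. A seeded simulator generates
every input type with ground truth, so the whole pipeline is testable
without instrument data.

It is written for systems-neuroscience users who have per-frame ROI
intensities (photometry), timestamped event logs (operant boxes,
lickometers), tracking output (trajectories), and sweep files
(current-clamp), and who want a tested, scriptable version of this
processing chain.

## The processing model

For background-subtracted series, with `c` the control-fluorophore series
and `s405`, `s473` the two signal-fiber channels:

1. `s473 ~ b0 + b1*c473`, `s405 ~ b0 + b1*c405` — keep residuals
   (laser-power correction),
2. `r473 ~ b0 + b1*r405` — keep residuals (shared-artifact correction via
   the isosbestic channel),
3. `z = (r - mean(r)) / sd(r)` over the session.

Both regressions are ordinary least squares with intercept. Peri-event
statistics operate on `z`: three-sample window means, window-mean
differences, trapezoidal AUC (z·s), Pearson correlations with Fisher-z 95 %
CIs, and seeded subsampling to equalize event counts across compared
categories. See the methods vignette
(`vignettes/photometry-pipeline.Rmd`) for the full model, parameter
defaults, and design rationale.

## Worked example

```r
library(photopeth)

# a 300 s synthetic session at the package's reference condition
sim <- simulate_standard_session(seed = 42, duration_s = 300)
tr  <- process_session(sim$session)
tr
#> <processed_trace> 4470 samples at 15 Hz (297.9 s)
#>   stage R^2: control 473 0.006, control 405 0.007, isosbestic 0.451
#>   dropped frames: 0, background (signal/control): 1/1.01

# align to the ground-truth transient onsets
pem <- align_events(tr, sim$truth$event_times_s, window = c(2, 5))
pem
#> <peri_event_matrix> 70 events x 106 lags (-2.00..5.00 s), 0 dropped
window_mean(pem, 0.45)   # near the kernel peak
#> <window_stat> mean z 1.7287 over 3 samples at lag 0.467 s (70 events)
window_mean(pem, -1.5)   # pre-event baseline
#> <window_stat> mean z -0.2132 over 3 samples at lag -1.533 s (70 events)

cor(tr$z, sim$truth$clean_transient_trace)  # 0.974
cor(tr$z, sim$truth$artifact_trace)         # 0.037
```

The isosbestic-stage R² of 0.45 is the share of the 473 nm residual
variance explained by the shared artifact and removed; the processed trace
tracks the ground-truth transient (r = 0.97) while being nearly orthogonal
to the injected artifact (r = 0.04). Event-aligned activity rises from a
baseline near −0.2 z to 1.7 z at the transient peak.

Operant sessions parse the same way end to end:

```r
log <- simulate_fr_session(behavior_sim_config(
  "FR5-5s", n_trials = 100, p_engage = 0.8, press_rate_hz = 1.5, seed = 7))
session_performance(parse_trials(log))
#>   stratum n_trials pct_completed pct_incomplete pct_omission
#> 1     all      100            70             12           18
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/photopeth-cli.R` (subcommands `process`, `align`, `trials`,
`bouts`, `ephys-features`, `tracing-summary`).

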