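---
title: "Denoising fiber photometry by sequential regression, and the analyses around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising fiber photometry by sequential regression, and the analyses around it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopeth)
```

## The measurement problem

A fiber-photometry rig of the kind this package targets multiplexes two
excitation lasers onto one implanted fiber: 473 nm light excites the calcium
indicator (GCaMP) at its calcium-sensitive wavelength, and 405 nm light
excites it at its isosbestic point, where emitted fluorescence is independent
of calcium. The lasers alternate frame by frame at 10 or 15 Hz per channel
(a 20 or 30 Hz frame train), so the two channels are sampled almost
simultaneously. A second fiber sits in a tube of dye and sees only the
excitation light, recording laser-power fluctuation. The recorded scalar per
frame is the mean pixel intensity over each fiber's region of interest.

The raw 473 nm series therefore mixes the quantity of interest — transient
calcium-dependent fluorescence — with camera background, slow photobleaching,
laser-power drift, and motion artifacts from cable flexion. The package's
processing chain, `process_session()`, removes these in the order in which
they enter the optical path:

1. **Demultiplexing.** Each 473 nm frame is paired with the immediately
   preceding 405 nm frame; the pair is timestamped at the 473 frame. Pairing
   (rather than interpolation) preserves causality and the sample count; at
   a 30 Hz frame train the two channel samples are 33 ms apart, well inside
   the indicator's kinetics. Unpaired edge frames are dropped and counted.
2. **Background subtraction.** The mean of the laser-off frames (a leading
   block in simulated sessions) is subtracted from both fibers' series.
3. **Control-fluorophore regression.** Each signal channel is regressed by
   ordinary least squares, with intercept, on its time-matched control-fiber
   series, and replaced by the residuals. This removes what the control
   fiber sees: laser-power fluctuation.
4. **Isosbestic regression.** The 473 nm residuals are regressed, with
   intercept, on the 405 nm residuals. Under the isosbestic assumption the
   405 channel carries the motion artifact and residual bleach but none of
   the calcium signal, so the residuals of this regression retain the
   transients.
5. **Session z-scoring.** The final residuals are standardized over the
   whole session, `(x - mean) / sd`, giving the processed trace its
   dimensionless z-score scale.

Three choices here were genuinely open and deserve a note. The regressions
include an intercept because the background/bleach offset must be absorbed
somewhere; without it the slope estimate is biased by the offset ratio.
Residuals are explicitly standardized because regression residuals are not
z-scores by themselves; z-scoring is applied per session (a per-block knob
would be easy to add, but session-level standardization is what gives
comparable peri-event amplitudes across a session). And bleaching gets no
dedicated detrending stage: both channels bleach together, so the two
regressions absorb it; `process_session(detrend = TRUE)` adds a linear
pre-detrend for pathological sessions but defaults off. Degenerate inputs
(constant control, constant residuals) fail loudly rather than returning
zeros; a constant control series can be tolerated explicitly with
`control_fallback = TRUE`, which mean-centers instead.

Two useful invariants follow from the construction and are asserted in the
tests: residuals are numerically orthogonal to their regressors (Pearson
correlation below 1e-10), and the full chain is invariant to a global
rescaling of all raw intensities, because both OLS stages and the z-score
are equivariant under scaling.

## What the simulator emulates

`simulate_photometry_session()` generates the frame stream the pipeline
consumes, with ground truth attached. The generative model, per channel
sample at time $t$:

- 473 nm: $F_{473}(t) = B + d(t)\,[b(t) + A\,c(t) + a(t)] + \varepsilon$
- 405 nm: $F_{405}(t) = B + d(t)\,[b(t) + a(t)] + \varepsilon$
- control fiber: $F_{ctl}(t) = B + d(t)\,L + \varepsilon$

where $B$ is the camera background (default 1), $b(t)$ a single-exponential
bleach (amplitude 2, tau 600 s), $a(t)$ the shared artifact, $d(t)$ the
multiplicative laser drift, $L$ the control-fluorophore brightness (5),
$A$ the transient amplitude (1), $\varepsilon$ iid Gaussian frame noise
(sd 0.05), and $c(t)$ the unit-amplitude transient trace: a
difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s, GCaMP6s-like)
convolved with the event train. The artifact enters both fluorescence
channels identically, sample for sample — that is the isosbestic contract
the second regression exploits — and the drift multiplies both fibers,
which is what the first regression exploits.

The reference condition used throughout the tests
(`simulate_standard_session()`) is a 300 s session at 15 Hz per channel with
Poisson transient onsets at 0.2 Hz, an artifact composed of a 0.5-amplitude
0.3 Hz sinusoid plus a Gaussian random walk (step sd 0.01), and a slow
±2 % laser drift. These values were fixed once as a plausible mid-range
condition: the artifact's power is comparable to the transient's, the frame
noise is 5 % of the transient amplitude, and the random walk gives the
artifact energy at the low frequencies where bleach and drift also live.
Under this condition the processed trace correlates with the ground-truth
transient above 0.9 and with the artifact below 0.05 (median over seeds) —
the quantities `scripts/acceptance.R` recomputes.

What the simulator does **not** emulate: hemodynamic contamination, focal
drift, indicator saturation and nonlinearity, non-shared (channel-specific)
artifacts, and any violation of the isosbestic assumption. Passing tests
therefore demonstrate that the chain removes what it models — shared
additive artifacts and multiplicative drift — not that it cures every
failure mode of real recordings.

## Peri-event analysis

`align_events()` snaps each event to the nearest trace sample (half-sample
ties resolve toward the earlier sample, a fixed rule rather than a
platform-dependent rounding) and stacks rows over a lag window; events whose
window leaves the session are dropped with a count. Summary statistics
follow the conventions of event-aligned photometry work:

- `window_mean()` averages **three consecutive samples** centered on the
  target lag (0.2 s at 15 Hz). Centering is symmetric by default;
  `placement = "leading"/"trailing"` shifts the window for users who anchor
  it differently, since the placement convention is not universal.
- `delta_z()` differences two such window means per event (e.g. the change
  from −0.7 s to +0.4 s around a press).
- `trace_auc()` integrates the z-scored trace trapezoidally between the
  samples nearest the bounds; adjacent intervals add exactly. At 15 Hz the
  trapezoid is within 0.2 % of fine-grid quadrature for the default kernel.
- `standardize_counts()` subsamples every compared category, seeded and
  without replacement, to the smallest category's size, so averages being
  compared rest on equal event counts.
- `correlate()` reports Pearson's r with the Fisher-z 95 % CI and a
  two-sided p (delegated to `stats::cor.test`).

The AUC window for latency correlations is a user choice (lever extension
to first press is the natural default for initiation analyses); the package
deliberately does not hard-code it.

## Operant, lick, and locomotor behavior

`parse_trials()` segments an event log at lever extension/retraction pairs.
Outcomes partition exhaustively: *completed* (press count reaches the
schedule ratio within the time limit, measured from lever extension),
*incomplete* (at least one press but fewer than required — one to four on
FR5), *omission* (no presses; defined as the forced complement since rate
reports require the three classes to partition). Initiation latency is
first press minus extension; retrieval latency is anchored at pellet
delivery (the causal anchor) to the next head entry.
`check_schedule_advancement()` implements the training criterion of at
least 30 completed trials on two consecutive sessions.

`detect_bouts()` segments lick trains by the standard microstructure rule:
a bout is two or more licks with every inter-lick interval strictly under
2 s; an interval of exactly 2 s splits the run. `detect_movement_epochs()`
uses speed hysteresis (onset 2 cm/s, offset 1 cm/s, minimum duration 0.5 s,
5-sample smoothing — all configurable, since tracking-software thresholds
vary) and `detect_approaches()` emits one event per outside-to-inside
crossing of a 5 cm radius around each target.

The behavioral simulator enforces exact "pseudo-random" proportions: light
trials are assigned by seeded shuffling of a fixed-proportion label vector,
so a 300-trial session at 33 % carries exactly 99 light trials.

## Intrinsic electrophysiology

Features extracted from current-clamp sweeps follow fixed operational
definitions: spike detection by local maxima above −20 mV with a ≥20 mV/ms
upstroke in the preceding 2 ms and a 2 ms refractory; AP threshold as the
voltage at the first sample whose forward dV/dt reaches 20 mV/ms (the
criterion value is configurable; 20 mV/ms is a common operational choice);
maximum firing rate as 5 ISIs over the span of the first six spikes of the
0.5 s step with the most spikes, undefined (flagged) below six; the
accommodation index as the mean local contrast of successive ISIs,
$A = \frac{1}{N-1}\sum_{i=2}^{N} \frac{ISI_i - ISI_{i-1}}{ISI_i + ISI_{i-1}}$,
which is 0 for constant trains, positive for adapting ones, and
antisymmetric under time reversal; input resistance as the steady-state
deflection (last 20 % of a −140 pA step, against a 50 ms pre-step baseline)
divided by the step current; and the rebound burst as spike count and mean
ISI in a 300 ms window after step offset. Sweeps that fail to sustain
firing through the step (depolarization block, heuristically: last spike
more than 30 % of the step before offset) are excluded from accommodation.
The sweep simulator superposes a piecewise-linear AP template (slow
10 mV/ms foot turning into a 100 mV/ms upstroke exactly 20 mV above the
local baseline) on an exponential membrane response, so thresholds, spike
times, and resistances all have closed-form ground truth.

## Tract-tracing quantification

`density_ratios()` forms, within each coronal slice, the ratio of
area-corrected densities (count / area) for CM : ipsilateral CL and
ipsilateral CL : contralateral CL, then averages slice ratios within each
case and case means across cases — in that order. A comparison is flagged
*strong* when the two densities differ by at least 40 % of the larger,
i.e. min/max ≤ 0.6, boundary inclusive; taking the larger density as the
reference makes the flag direction-agnostic (the convention had to be fixed
one way; the symmetric form is recorded here as the package's choice).
Zero-denominator slices are excluded with a warning.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run on deliberately modest sizes
chosen as adequate for the properties they check: 20 seeded 300 s sessions
for artifact-rejection medians, 1,000 trials for classification, 1,000
random lick trains against a brute-force oracle, 50 fixture sweeps, 100
Poisson tracing cases, and 12 seeds per alignment condition for the
direction-of-effect check. Tie-breaks (event snapping toward the earlier
sample), strictness conventions (ILI < 2 s, flag boundary inclusive), and
degenerate-input behavior (errors, not silent zeros) are all fixed and
tested explicitly.

Known limitations: the pipeline implements exactly this two-stage-regression
scheme — no ΔF/F, baseline-percentile, or hemodynamic corrections; omnibus
statistics (ANOVA families and post-hoc corrections) are out of scope, the
package exporting instead the per-animal summary tables such tests consume;
and the simulator's realism bounds what the tests can certify, as noted
above.
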