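---
title: "stopERSP: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stopERSP: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **stopERSP**, the
parameters that matter, the numerical conventions, and the places where a
genuinely open design choice had to be made. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The task model

The anticipated-response stop signal task is simulated trial by trial.
One trial is: fixation (2000 ms), a "get set" cue, a self-paced button
press (fixed at 600 ms after the cue in simulation), a 1400 ms pre-motion
delay, then 1000 ms of target motion. On go trials the button must be
released 700–800 ms after motion onset (releases before 700 ms are "Too
early!", after 800 ms or never "Too late!"). On stop trials a stop cue
appears at the stop signal delay (SSD) and the button must stay held.

`taskConfig()` defaults encode the studied design: 4 mixed blocks of 40
trials at a 2:1 go:stop ratio. 40 is not divisible by 3, so blocks
alternate 13/14 stop trials (54 stop, 106 go overall) — the closest
deterministic integer realization. A practice phase (10 go-only, 10
stop-only, 20 mixed trials) is simulated, flagged, and excluded from all
summaries.

**Staircase.** Each block restarts the SSD at 500 ms; a successful stop
moves it 50 ms later (harder), a failure 50 ms earlier, clamped to the
300–700 ms cue range of the task display. The success-increments
direction is forced by the anticipated-response geometry: a later cue
leaves the stop process less time before the planned release, so it makes
stopping harder, and the staircase converges to the 0.5 success rate the
procedure is designed to reach.

**Subject model.** The horse race: each trial draws a planned release
latency and (on stop trials) a covert stop latency, both truncated normal
(> 0); the stop wins iff `ssd + ssrt ≤ planned release`. Defaults
(`goMu = 798`, `goSigma = 25`, `ssrtMu = 250`, `ssrtSigma = 35` ms) place
the staircase equilibrium near `798 − 250 = 548` ms, reproducing the
published group means of this task, and give a go-success rate near 0.5.
Go omissions (rate 0 by default) are classified late and excluded from
GO-RT, because the means method needs realized latencies. Release
latencies of *failed stop* trials are recorded but do not enter GO-RT:
only go trials contribute (flagged as a sensitivity point; the package
exposes the raw logs so the alternative is one line of user code).

**A property worth knowing.** The staircase's *stationary* success rate
is 0.50 (verified in the tests), but the per-block restart at 500 ms sits
one 50 ms step below the ~548 ms equilibrium, so the first two or three
stop trials of every block are easier than equilibrium. Over 4 × 13–14
stop trials this inflates the *session mean* probability of inhibiting to
≈ 0.53–0.54 — which is exactly where empirical cohorts on this task land
(0.54 ± 0.04–0.06). The package reports the honest finite-block mean; it
does not discard "burn-in" stop trials.

# The synthetic EEG generator

The generator emits what the out-of-scope recording, preprocessing and
source-localization stages would deliver: clean per-ROI single-trial
source time series at 1000 Hz for RSFG, RMFG and RIFG, spanning fixation
through the end of motion, with the last 200 ms of fixation available as
the dB baseline.

Each ROI trial is the sum of

* a weak 1/f^χ Gaussian background (χ = 1, total variance 0.1), made by
  spectrally shaping white noise; and
* an oscillator bank: eleven sub-bands tiling 3.5–50 Hz with edges
  aligned to the canonical band boundaries (θ 3.5–7.5, α 7.5–12.5,
  β 12.5–30, γ 30–50 Hz). Each trial, every sub-band contributes one
  constant-envelope sinusoid with frequency drawn uniformly in the
  sub-band and a random phase; amplitudes fall off as √(10/f).

This *quasi-harmonic* design is deliberate. With Gaussian narrowband
activity, single-trial wavelet power is exponentially distributed and the
trial average of per-trial log power acquires a −1 to −2.5 dB offset
(E[log P] < log E[P]); injected effects could then never be recovered at
fraction-of-a-dB precision from per-trial dB maps. Constant-envelope
components make single-trial band power near-deterministic, so a
requested power change is expressed faithfully. The cost is realism:
real EEG has Rayleigh-distributed narrowband amplitudes, larger
trial-to-trial power variance, and non-stationary background. Passing
recovery tests therefore demonstrates correctness of the *measurement
chain*, not that effects of this size are detectable in real recordings
at these trial counts.

**Effect injection.** `erspEffect()` describes a band × time-window power
change in dB, locked to motion onset or to the trial's stop signal, for
one ROI and group ("A", "B" or both). Amplitudes of all oscillator
components in the band — and the band-limited part of the background —
are multiplied by `10^(deltaDb/20)` inside the window, so *power* changes
by `deltaDb`; 50 ms raised-cosine ramps avoid spectral splatter.
Scaling the background too matters: with a 10 dB suppression, even a 2%
unscaled in-band floor would truncate the measured change to ≈ −9.2 dB.

**What the single-trial dB offset means in practice.** Even with this
generator, averaged per-trial dB maps retain a small negative offset
wherever two components beat within one wavelet's bandwidth. The offset
is identical across trials, conditions and groups, so it cancels exactly
in group-difference maps, in dB-change contrasts against a seed-paired
null run, and in the permutation statistics (which compare groups). The
tests measure effect recovery through those contrasts; absolute
single-condition map values carry the offset and are not interpreted to
fractions of a dB.

# Wavelet decomposition and dB normalization

`buildWavelets()` constructs Gaussian-windowed complex exponentials with
σ_t = cycles/(2πf), truncated at 3.5 σ_t and normalized to unit energy
(white noise of variance σ² then has expected power σ² at every
frequency). The default grid is 3–50 Hz in 0.5 Hz steps — 95 wavelets.
The cycle rule is unspecified in the source analyses, so it is a
configuration knob: the default rises linearly from 3 cycles at 3 Hz to
10 at 50 Hz (the usual time/frequency trade-off); a constant rule is
available, and resolution-sensitive experiments (e.g. the per-band
recovery tests) use constant higher cycle counts.

Convolution is frequency-domain multiplication with explicit
edge-validity bookkeeping: epochs carry a symmetric pad beyond the
analysis span, and `tfPower()` refuses any wavelet whose half-width
(3.5 σ_t) exceeds the pad — edge-contaminated samples can never enter an
analysis window. The default 650 ms pad covers the slowest default
wavelet (3 Hz, 3 cycles, 557 ms).

dB normalization is per trial and per frequency:
`dB(f,t,i) = 10·log10(P(f,t,i) / mean_t' P_baseline(f,t',i))`, with the
baseline the last 200 ms of fixation of the same trial. Whether the
source analyses used per-trial or trial-averaged baselines is not stated;
both are implemented (`mode = "trial"` / `"average"`), per-trial is the
default (it preserves trials as exchangeable units, which the permutation
test relies on), and the acceptance suite runs under the default.
`dbDenormalize()` inverts the transform exactly.

**Spectral and temporal smearing.** A Morlet family cannot represent a
brickwall effect edge: a band-limited effect is attenuated within
~1.5–2 σ_f of its band edge and within ~ramp + 2.5 σ_t of its window
edge. Recovery is therefore measured on the effect's plateau (stated
margins in each test), and γ-band effects in a 0–300 ms window are
recovered to within ±0.5 dB there. Narrow bands (α is only 5 Hz wide)
need higher cycle counts for a clean interior — another reason the cycle
rule is exposed.

# The cluster-mass permutation test

The master array pools the dB values of all trials of both groups
(frequency × time × trials). Per pixel, a pooled-variance two-sample
*t* across trials (df = nA + nB − 2; an ε-guard handles zero-variance
pixels, which occur only with degenerate constant input). Design
choices, in order of consequence:

* **Null summary = maximum cluster mass per permutation.** The
  description "masses for each of the 1000 permutations" does not name a
  summary; the max-statistic is the standard familywise-valid choice and
  is the default (a pooled-all-masses variant sits behind
  `pooled = TRUE`). The type-I tests confirm the resulting per-ROI
  familywise rate ≈ α/3.
* **8-connectivity** in the time-frequency plane, matching the default of
  the 2-D connected-component routine the source analyses cite. Labels
  are assigned in row-major discovery order and are validated against an
  exhaustive flood-fill oracle.
* **Two-tailed pixel threshold** at p = 0.05: both ERD and ERS
  differences are scientifically expected, so |t| is thresholded.
* **Corrected threshold** = the 100(1 − α/nRois) percentile of the null
  masses — 98.3 for three ROIs at α = 0.05 — computed at the exact
  probability with linear interpolation at position n·p of the sorted
  masses (so a {1..1000} null gives 983.33).
* **t, not Z.** Thresholding and masses use t statistics; permutation-Z
  maps ((observed − null mean)/null SD) are a diagnostic by-product of
  the same machinery, not part of inference.
* **Trials are pooled across subjects within group** (fixed effects over
  trials), exactly as the master-array construction implies. This treats
  trials as exchangeable and will overstate evidence in the presence of
  strong between-subject variability; a subject-level random-effect
  permutation scheme is explicitly out of scope. Likewise, label
  shuffling is free over the trial dimension — it does not preserve
  subject boundaries — as the master-array description states.

Per-cluster corrected p is the fraction of null masses at or above the
observed mass. `extractMaskedPower()` reduces each subject's
trial-averaged map to the mean dB over a significant-cluster mask — the
scalar entering correlations.

# Clinical statistics

"Age-adjusted correlation" is implemented as the first-order partial
Pearson correlation: residuals of both variables after least-squares
regression on age (plus intercept), correlated; p from
t = r√((n−k−2)/(1−r²)). The residual route is cross-checked against the
closed-form recursive formula to 1e-10. A constant covariate is dropped
(the estimate then equals the plain Pearson r).

FDR correction is Benjamini–Hochberg over exactly the three scales
(tic severity, obsessive-compulsive, ADHD) per ROI analysis, and the
correlation stage only runs where a significant case–control cluster
exists — mirroring the gating of the source analyses. SSRT versus tic
suppressibility is a plain Pearson correlation, reported unadjusted.

Descriptives use the n−1 standard deviation and midpoint medians for
even n. On the bundled 14-subject cohort table the tic-severity column's
midpoint median is 22.5; published prose rounds it to 23. The tests
assert the computed 22.5.

# The pipeline and the scales things run at

`runPipeline()` executes simulate → decompose → cluster-test → correlate
from one seeded configuration, writing TSV/CSV tables, JSON provenance
(seed, config MD5, package version) and a log; identical configurations
reproduce byte-identical outputs, and dB master arrays are cached so the
permutation stage can be re-run with different α or nRois without
re-simulation. The motion-locked statistical window is 0–300 ms — before
300 ms the stop cue cannot yet have appeared, so all trials are
uncontaminated preparation — and the stop-locked window defaults to
0–500 ms (the epoch spans, −500..1000 ms motion-locked and −500..800 ms
stop-locked, are configurable defaults, not asserted facts about the
source analyses). Master arrays decimate the time axis to 10 ms steps;
wavelet power is smooth at the σ_t scale, so this loses nothing the
statistics can see.

Problem sizes in the shipped tests were chosen to make the checks sharp
while keeping the suite brisk: 200 sessions for staircase and SSRT
calibration, 120–200 trials for dB-recovery, 500 null datasets of
30 × 50 × 80 with 500 permutations for type-I calibration, 200 trials
per group with 1000 permutations for the detection/recovery run, and 500
cohorts of n = 14 for correlation recovery. `validateSuite()` re-runs
the same checks at reduced scale (100 datasets, 200 permutations by
default) as a machine-readable calibration report.

# Known limitations

* The generator's constant-envelope oscillators understate single-trial
  power variability relative to real EEG (see above); detection power on
  synthetic data is optimistic.
* No tic or EMG artifacts, no sensor-level data, no volume conduction or
  source leakage between ROIs: the data contract starts at clean ROI
  epochs.
* The trial-pooled test is a fixed-effects analysis; generalization to a
  population requires subject-level modelling that is out of scope here.
* Feedback-driven strategy shifts and inter-trial-interval effects are
  not modelled; the subject model is stationary within a session.
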