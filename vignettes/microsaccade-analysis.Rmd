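---
title: "Microsaccade detection and pre/post study analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsaccade detection and pre/post study analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsacc)
```

## The measurement problem

During attempted fixation the eyes produce microsaccades: small, fast,
binocular jerks of roughly 1–120 arcmin lasting about 6–25 ms, at 1–2 per
second. Their rate is of interest in two roles. As a *state* measure, the
rate drops when collicular excitation is reduced — for instance after
caffeine, which blocks the adenosine receptors expressed in the superior
colliculus — so a pre/post rate contrast can index a drug's central effect.
As a *trait* measure, a person's rate is highly stable across sessions, so
the pre/post correlation across participants quantifies its reliability as
an individual-difference measure.

`microsacc` implements the full chain for such studies: detection of
binocular microsaccades from raw gaze samples, the session-level contrast
statistics, and two sensitivity analyses (robustness to detection
parameters; stability under reduced trial counts), together with a
simulator that generates binocular gaze with known ground truth.

## Detection model

Detection follows the standard median-based velocity-threshold scheme for
fixational eye movements.

**Velocity.** Positions (always in degrees; pixel input is converted with a
per-axis arctangent given the display geometry) are differentiated with a
smoothing moving-difference kernel. With the default 5-sample window at
sampling interval $\Delta t$:

$$v_n = \frac{p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}}{6\,\Delta t}$$

Samples one step from either edge fall back to the central difference and
the two extreme samples are assigned zero velocity. The kernel is exact on
affine signals and suppresses sample-to-sample sensor noise.

**Threshold.** Saccades make the velocity distribution heavy-tailed, so the
spread is estimated robustly per trial, per eye and per axis as
$\sigma = \sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$, and the
detection threshold is $\eta = \mathrm{vfac}\cdot\sigma$. A sample is
suprathreshold when $(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$ (an elliptic
criterion combining both axes). Thresholds are estimated within each trial
independently, which keeps trials exchangeable for the bootstrap; if a
trial's spread falls below $10^{-10}$ deg/s the trial is flagged degenerate
(tracker dropout) and excluded rather than scored as zero events.

**Events.** Maximal runs of suprathreshold samples of at least `mindur`
samples become monocular events; runs separated by at most `merge_gap`
subthreshold samples may be merged first (`merge_gap = 0` by default — no
overshoot merging, the parameter exists so the choice is explicit and
testable). Events overlapping invalid samples (blinks, padded by 10 samples
on each side to suppress lens-slip velocity artifacts at blink edges) are
discarded. Left and right events whose sample intervals share at least
`min_overlap` samples are paired greedily in onset order, one-to-one; the
binocular event spans the union interval and takes its kinematics (peak
velocity, displacement, amplitude) from the eye with the larger peak
velocity. The binocular count is the per-trial unit of analysis (a
`mean_LR` count mode is available as an alternative).

Key parameters, with defaults chosen for 500 Hz binocular recordings:

| parameter | default | meaning |
|---|---|---|
| `vfac` | 5 | threshold as a multiple of the median-based spread |
| `mindur` | 6 samples (12 ms) | minimum event duration |
| `velocity_window` | 5 samples | velocity kernel width |
| `min_overlap` | 1 sample | binocular pairing criterion |
| `merge_gap` | 0 samples | run merging before the duration test |

Sample indices are 0-based and event intervals inclusive, so
duration $= (\mathrm{offset} - \mathrm{onset} + 1)/f_s$. Event amplitude is
the Euclidean norm of the per-axis extents (max − min over the interval),
which exceeds the net displacement for overshooting trajectories.

## Study statistics

Counts are converted to rates (events/s) — the per-second normalization
makes values comparable across trial durations and matches the conventional
1–2 per second scale. Per participant and session, the mean rate over
retained trials is the participant's score. The pre/post contrast is then:

- two-sided paired t-test on the participant means ($t$, df $= n-1$);
- Cohen's d in three variants, since paired designs admit several and
  published values often do not say which was used: **pooled**
  $d = (\bar x_{pre} - \bar x_{post}) / \sqrt{(s_{pre}^2 + s_{post}^2)/2}$
  (the headline default), **pre_sd** (divide by $s_{pre}$), and **dz**
  (divide by $s_{diff}$; satisfies $d_z\sqrt{n} = t$ exactly). Reports
  should quote all three, and `ms_study()` computes all three;
- the Pearson correlation between pre and post participant means, the
  trait-stability claim, with the usual $t$-transform p-value.

`trial_timecourse()` additionally averages rates across participants per
trial index, to inspect within-session drift of the rate.

## Sensitivity analyses

**Parameter sweep.** Both `mindur` and `vfac` change which samples form
events, so no shortcut over the raw data is sound: `parameter_sweep()`
re-runs detection from the raw samples for every cell of the (default)
mindur 2..11 × vfac 3..8 grid and records the effect size and the number of
excluded trials per cell. Cells where fewer than two participants retain
trials are marked missing rather than zero.

**Trial-count bootstrap.** To ask "would fewer trials have sufficed?", for
each $k$ the per-trial rates are resampled with replacement — $k$ trials
independently for every participant and session — and d and r are
recomputed across participants; the per-$k$ mean and 2.5/97.5 percentile
bounds over `n_boot = 1000` replicates form the curves. Participants are
deliberately *not* resampled: the question posed concerns trial count, and
resampling participants would conflate the two sources of variance.
Percentile (not BCa) intervals are used, matching the plain
confidence-range construction. Degenerate replicates (zero variance in a
required denominator) are redrawn from the continuing stream and counted.
The draw stream is documented (ascending $k$; participants in sorted order;
pre then post; one `sample.int` call per participant-session filled
replicate-major), so any sub-curve is exactly reproducible from the seed.

## The simulator

The generator's defaults emulate a two-session caffeine-style study: 22
participants × 2 sessions × 60 trials of 5.5 s at 500 Hz.

- **Base rates.** Participant $i$ draws a pre-session rate from
  $\mathcal N(1.4, 0.45^2)$ events/s (clamped at zero); the post-session
  expected rate is the pre rate × `post_rate_multiplier` (default 0.85, a
  ~15% reduction). Per-trial rates add Gaussian jitter (sd 0.2/s, clamped
  at zero) to create the within-participant variance the bootstrap needs. A
  participant whose base rate is exactly zero stays silent: jitter models
  fluctuation of an active generator, not spontaneous activation.
- **Event times.** Onsets follow a dead-time renewal process: gaps are a
  hard refractory interval $\tau = 0.15$ s plus an exponential wait of
  intensity $\lambda = r/(1 - r\tau)$. This is exactly a homogeneous
  Poisson stream of intensity $\lambda$ thinned non-paralyzably by the
  refractory period, with $\lambda$ corrected so the *realized* rate equals
  the nominal $r$ — so ground-truth rates are directly comparable to the
  configured ones.
- **Waveforms.** Each event is a raised-cosine velocity pulse: total
  displacement equals the amplitude, peak velocity follows a linear main
  sequence $v_{peak} = 80 A$ (deg/s per deg), hence a fixed duration
  $2/80$ s = 25 ms (12–13 samples at 500 Hz) — the upper end of the
  empirical 6–25 ms range, chosen so that a `mindur = 6` suprathreshold run
  survives the kernel's smoothing even for small events. Amplitudes are
  lognormal with log-mean $\log 0.55$ and log-sd 0.25 (median 33 arcmin,
  ~99% above 0.3°), directions uniform. The published study reports no
  amplitude distribution, so these are conventional oculomotor values, not
  fitted ones.
- **Drift and noise.** Between events the gaze follows a discretized
  mean-reverting Ornstein–Uhlenbeck process (stationary sd 0.05°, reversion
  2/s) — bounded drift mimics maintained fixation over 5.5 s trials, where
  a pure random walk would wander off target. Drift and event displacement
  are identical in the two eyes (conjugate); each eye adds independent
  Gaussian sensor noise (sd 0.01°, a typical video-tracker noise floor).
  With probability 0.05 a trial contains one blink: a 0.1–0.3 s run of
  invalid samples in both eyes.
- **Randomness.** One root seed; every participant-level and trial-level
  draw uses a child stream derived by a fixed counter scheme
  (`child_seed(root, participant, session, trial)`), so identical configs
  are bit-reproducible and any subset can be regenerated in isolation.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: binocular disconjugacy, saccadic overshoot and
glissades, amplitude-dependent durations, smooth pursuit, square-wave
jerks, pupil-size artifacts, calibration drift, and — importantly — any
session-to-session *trait instability* or measurement non-stationarity
beyond trial jitter. Because participants' base rates are perfectly
preserved up to the multiplier, simulated pre/post correlations (~0.98) and
paired t statistics exceed those of real studies (~0.89 and ~4.4 in
comparable published data); recovery tests validate the pipeline's
statistical machinery, not the biological variance structure.

## Numerical conventions and edge cases

- Detection is translation-invariant and mirror-symmetric by construction;
  raising `vfac` or `mindur` can only remove events.
- The velocity-spread floor ($10^{-10}$ deg/s) converts constant traces
  into explicit degenerate-trial exclusions with a logged reason.
- Cohen's d returns 0 when the mean difference is exactly zero (the 0/0
  limit of all variants); a zero denominator with a nonzero difference is
  an error.
- Tables are written tab-separated with numerics at full `%.17g` precision,
  so write/read round trips are exact.
- Medians use an exact partial-sort; the threshold estimator equals the
  naive sort-based computation to machine precision.

## Problem sizes used in validation

The package's test suite exercises the full study regime where the claim
depends on it (effect recovery: 20 seeded replicates of 22 × 2 × 60 trials;
detection/ground-truth agreement; bootstrap narrowing at `n_boot` 200) and
reduced regimes elsewhere (oracle-equivalence fixtures, 50-trial
monotonicity checks, toy pipelines), a balance chosen to keep the suite
informative at a few minutes of runtime. The acceptance script runs the
complete pipeline — full sweep grid and `n_boot = 1000` bootstrap — at the
default regime.

## Limitations

Real deposited recordings carry vendor-specific preprocessing (blink
reconstruction, drift correction) that this package intentionally leaves
out of scope; reproducing published numbers from raw deposits therefore
depends on feeding the interchange-format samples produced by an upstream
parser. The binocular pairing rule (greedy, one-to-one, union span) is one
reasonable pinning of an under-documented convention; alternative cluster
rules can shift counts by a few percent, which is precisely what the
parameter sweep is for.
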