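# microsacc

Binocular microsaccade detection and pre/post session analysis in R.

Microsaccades are tiny involuntary saccades (roughly 1–120 arcmin, 6–25 ms,
1–2 per second) produced during attempted fixation. Because their rate is
modulated by the superior colliculus, a drop in microsaccade rate after a
pharmacological manipulation (e.g. caffeine, an adenosine-receptor
antagonist) can serve as a non-invasive *state* measure of collicular
excitability, while the stability of a person's rate across sessions makes
it a candidate *trait* measure. `microsacc` implements the full analysis
chain for such pre/post fixation studies, together with a seeded simulator
so every stage can be validated against ground truth without recorded data.

## What it computes

**Detection.** Gaze velocity is estimated with a 5-sample moving-difference
kernel, v<sub>n</sub> = (p<sub>n+2</sub> + p<sub>n+1</sub> − p<sub>n−1</sub> −
p<sub>n−2</sub>) / (6Δt). Per trial and per eye, a robust velocity spread

σ = sqrt( median(v²) − median(v)² )

sets elliptic thresholds η = vfac·σ (default `vfac = 5`); a microsaccade is a
run of at least `mindur` consecutive samples (default 6, i.e. 12 ms at
500 Hz) with (v<sub>x</sub>/η<sub>x</sub>)² + (v<sub>y</sub>/η<sub>y</sub>)² > 1.
Left- and right-eye events overlapping in time are paired greedily,
one-to-one, into binocular events — the count unit used downstream.

**Study statistics.** Per-trial binocular counts become rates (events/s);
per-participant session means feed a two-sided paired t-test, Cohen's d
(pooled, pre-SD and difference-score d<sub>z</sub> variants, all reported),
and the pre/post Pearson stability correlation, plus a per-trial-index
timecourse.

**Sensitivity.** `parameter_sweep()` re-runs detection from the raw samples
for every (mindur, vfac) combination (defaults 2..11 × 3..8) and maps the
effect size over the grid. `bootstrap_trial_curves()` asks how stable d and
r would be with fewer trials: for each k it resamples k trials per
participant and session with replacement and reports percentile 95%
intervals over 1000 replicates.

**Simulation.** `simulate_study()` generates a full binocular study —
mean-reverting (Ornstein–Uhlenbeck) drift, raised-cosine microsaccade
waveforms on a linear main sequence, a refractory event process whose
realized rate equals the nominal rate, per-eye sensor noise, blinks — with
per-participant base rates, a configurable post-session rate multiplier and
complete ground truth.

## Worked example

```r
library(microsacc)

cfg <- sim_config(n_participants = 8, n_trials_per_session = 20, seed = 7)
sim <- simulate_study(cfg)                      # gaze study + ground truth
det <- detect_study(sim$study)                  # default vfac 5, mindur 6
fit <- ms_study(rates_from_detection(det, cfg$trial_duration))
summary(fit)
#> Pre/post microsaccade rate analysis (8 participants)
#>   pre  1.727 events/s (sd 0.411)
#>   post 1.502 events/s (sd 0.381)
#>   paired t(7) = 9.175, p = 3.76e-05
#>   Cohen's d (pooled) = 0.568
#>   pre/post r = 0.988, p = 4.68e-06
#>   d variants: pooled 0.568, pre_sd 0.547, dz 3.244
#>   trials used per session: 20-20

event_recovery(det, sim$truth, cfg$sampling_rate)$f1
#> [1] 0.998
```

The fit says: the simulated intervention reduced the mean rate from 1.73 to
1.50 events/s (the generator's post multiplier is 0.85), the reduction is
highly reliable across participants (paired t), of moderate standardized
size (pooled d), and individual rates are strongly preserved across
sessions (r = 0.99) — and the detector recovered 99.8% of the injected
events.

Every stage is also available from the shell:

```sh
Rscript inst/scripts/microsacc-cli.R run-all --out results_dir --seed 1
```

## Vignette

`vignettes/microsaccade-analysis.Rmd` documents the detection algorithm and
its parameters, the statistical model, the simulator's design (and what it
deliberately does not emulate), and the package's numerical conventions.
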