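# lrtceeg

Single-trial long-range temporal correlation (LRTC) analysis of broadband
EEG during movement and motor imagery.

## What problem this solves

EEG combines narrowband oscillations with an arrhythmic broadband
component whose autocorrelation decays as a power law. That decay is
summarized by the Hurst exponent *H* (DFA scaling exponent): *H* = 0.5
means no temporal memory, *H* ∈ (0.5, 1) persistent long-range memory.
Classically, LRTC is estimated once per long recording from the amplitude
envelope of a narrowband rhythm, which cannot track within-trial
dynamics. This package estimates *H* of the broadband (0.5–45 Hz) signal
on **causal 2 s sliding windows stepped every 100 ms**, yielding a
single-trial time course *H*<sub>BB</sub>(*t*) that rises during movement
and motor imagery and can serve as a feature for brain–computer
interfaces — and contrasts it with the alpha (8–13 Hz) envelope exponent
*H*<sub>alpha</sub>, computed on cross-trial stitched segments, which
moves the opposite way during a task.

For users: neural signal-processing and BCI researchers who want a
tested, seedable implementation of sliding-window DFA with its validation
cascade, plus a synthetic generator with known ground truth to calibrate
against.

## The method

For a window *x*(1..*N*): integrate
*y*(*k*) = Σ<sub>*i*≤*k*</sub>(*x*(*i*) − x̄), split *y* into
⌊*N*/*n*⌋ boxes per box size *n* (laid from both ends, results
averaged), remove a least-squares line per box, and take
*F*(*n*) = RMS of the residuals. *H* is the OLS slope of log₂*F* vs
log₂*n* over 25 box sizes in [10, *N*/4]. A three-stage cascade
validates that *Ĥ* > 0.5 reflects genuine LRTC: (1) sample-shuffled
surrogates must scale like white noise, (2) ARFIMA (fractional
differencing by *d* = *Ĥ* − 0.5) must beat ARMA by AIC, (3) ML-DFA must
rank the linear model best on the log-log fluctuation plot. Per-window
task-vs-rest statistics use Mann–Whitney U tests (t-test when both
samples pass a KS normality screen), and per-window LDA on the C3/Cz/C4
exponents yields accuracy time courses against an exact binomial chance
threshold.

## Worked example

```r
library(lrtceeg)

# a synthetic asynchronous-tap dataset: 40 task + 40 rest trials,
# broadband H 0.60 -> 0.75 during the task, alpha-envelope H 0.80 -> 0.65
cfg <- pipeline_config(synth = list(n_trials_per_condition = 40,
                                    task_start = -1.5, task_duration = 3),
                       validate_n_windows = 0)
res <- run_pipeline(cfg, "demo_out")

res$classifier
#> classifier_timecourse: peak 85.8% at 1.99219 s (threshold 65.0%),
#>   first crossing -0.710938 s
res$detect$lead_time
#> [1] 0.7109375
mean(res$stitched$h_alpha_rest) - mean(res$stitched$h_alpha_task)
#> [1] 0.1495926
```

Reading: the per-window LDA on smoothed *H*<sub>BB</sub> features peaks
at 85.8% accuracy ~2 s after movement onset — well above the exact
binomial 95% chance bound for 40 trials (65.0%) — and first exceeds that
bound 0.71 s *before* the onset, i.e. the movement is predicted from
pre-onset broadband LRTC. The stitched alpha-envelope exponent drops by
~0.15 during the task while the broadband exponent rises: two scale-free
processes moving in opposite directions.

Lower-level entry points: `gen_dataset()`, `bandpass()`,
`sliding_windows()`, `h_timecourse()`, `validate_lrtc()`,
`significance_timecourse()`, `stitch()`/`stitched_dfa()`,
`within_subject_cv()`/`loso_cv()`. A command-line front end is installed
at `inst/cli/lrtceeg.R` (`simulate` and `run` subcommands, JSON config).

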