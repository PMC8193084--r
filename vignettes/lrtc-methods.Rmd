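---
title: "Methods: single-trial broadband LRTC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial broadband LRTC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lrtceeg)
```

## The problem

EEG mixes narrowband oscillations (e.g. the 8–13 Hz alpha rhythm) with an
arrhythmic broadband component whose autocorrelation decays as a power law.
The strength of that decay — the long-range temporal correlation (LRTC) —
is summarized by the Hurst exponent $H$: $H = 0.5$ means no memory,
$H \in (0.5, 1)$ persistent long memory. Classical LRTC analysis estimates
one $H$ per long recording from the amplitude envelope of a narrowband
oscillation, which hides within-trial dynamics. This package instead
tracks $H$ of the *broadband* (0.5–45 Hz) signal on causal 2 s windows
stepped every 100 ms, producing a single-trial time course $H_{BB}(t)$
usable as a feature for movement detection, and contrasts it with the
slow alpha-envelope exponent $H_{alpha}$ computed on cross-trial stitched
segments.

## Detrended fluctuation analysis

For a window $x(1..N)$ the mean-centred integrated profile is
$y(k) = \sum_{i \le k} (x(i) - \bar x)$. For each box size $n$ the profile
is split into $\lfloor N/n \rfloor$ non-overlapping boxes, a least-squares
line is removed per box, and $F(n)$ is the RMS of the residuals. Because
$N$ is generally not divisible by $n$, boxes are laid both from the start
and from the end of the profile and the two RMS values are averaged — so
trailing samples excluded in one direction are covered by the other. $H$
is the OLS slope of $\log_2 F$ against $\log_2 n$.

Numerical choices:

* **Box grid.** 25 sizes, log2-equidistant in $[10, \lfloor N/4 \rfloor]$,
  rounded to integers and de-duplicated (the realized count is reported,
  never padded). For the 256-sample window this is $[10, 64]$ samples
  (78 ms–0.5 s), inside the admissible range
  $[\max(k{+}2, F_s/F_{max}), \min(N/4, F_s/F_{min})]$ for linear
  detrending ($k{=}1$) of a 0.5–45 Hz band at 128 Hz.
* **Fit.** Unweighted OLS on the log-log points; no per-scale weighting.
* **Degenerate windows** (constant or exactly linear input give
  $F(n) = 0$) raise an error in `dfa_exponent()`; `h_timecourse()`
  converts them to `NA`, logs a warning, and group statistics exclude
  them rather than impute.
* **Taper.** Each 2 s window is Hanning-tapered before DFA/ARFIMA to
  suppress edge effects (the taper is included in $x$ before the profile
  is formed). Tapering slightly raises short-window $\hat H$ (~+0.02 at
  $H = 0.75$) but improves monotone recovery; stitched windows are *not*
  tapered, since zeroed seams would corrupt long-timescale fluctuations.

Per-trial $\hat H$ sequences are smoothed with a causal exponential filter
$s_k = \alpha v_k + (1-\alpha)s_{k-1}$; the smoothing constant is not
prescribed anywhere authoritative, so the package default is
$\alpha = 0.3$ (a compromise between noise reduction and the ~2–3-window
group delay any causal smoother adds), exposed as `alpha_smooth`.

## Timescales and stitching

Broadband fluctuations are informative only below a crossover near 2 s:
the 0.5 Hz high-pass removes slower power, so stitched *broadband*
exponents use 0.1–2 s boxes. Alpha-envelope fluctuations live on slower
scales, so $H_{alpha}$ requires long segments: the time-aligned 2 s
window from every trial is concatenated (40 trials → 80 s, 22 → 44 s)
and DFA runs on 2–20 s (80 s segments) or 2–8 s (44 s) boxes. Bounds in
seconds are bracketed to powers of two
($2^{\mathrm{round}(\log_2 f_s t_{min})}$ to
$2^{\lfloor \log_2 f_s t_{max} \rfloor}$), reproducing the conventional
$[2^8, 2^{11}]$ and $[2^8, 2^{10}]$ sample brackets at 128 Hz. Stitching
assumes the windows at one latency share statistics across trials;
concatenation seams are the price, and the envelope (non-negative,
slowly varying) tolerates them well.

## The validation cascade

A finite $\hat H > 0.5$ alone does not establish LRTC. Three stages:

1. **Surrogate test** — sample shuffling destroys all temporal structure;
   shuffled windows must scale like white noise ($\hat H \approx 0.5$) and
   a Mann–Whitney U test must separate original from shuffled exponents.
2. **ARMA vs ARFIMA** — short-range (exponentially decaying) dependence
   is distinguished from long-range dependence by fitting ARMA$(p, 0)$,
   $p \in \{1..10\}$ selected by AIC, to the raw window, and to the
   window fractionally differenced by $d = \hat H_{BB} - 0.5$ (binomial
   weights $w_0 = 1$, $w_j = w_{j-1}(j-1-d)/j$, truncated at the window
   length; $d$ clamped to $[-0.49, 0.49]$). The ARFIMA branch's AIC
   carries a one-parameter penalty for $d$ — the source method is silent
   here, and omitting it would bias the comparison toward ARFIMA. Orders
   are selected independently per branch. ARMA estimation uses
   `stats::arima` (exact Gaussian likelihood, state-space), with a
   conditional-sum-of-squares fallback on non-convergence.
3. **ML-DFA** — the log-log fluctuation plot is fit with polynomials of
   order 1–5, $a + be^{cu}$, $a + b\ln u$, and $a + b\sqrt u$; candidates
   are ranked by AIC and BIC with a Gaussian likelihood built from the
   residual variance ($k$ = coefficients + 1). A linear winner marks a
   potential power law; when the quadratic wins, the diagnostic
   $|a_2/a_1|$ quantifies how far from linear the plot is.

**Known limitation.** The original ML-DFA construction normalizes the
fluctuation plot into a likelihood; that construction is deliberately not
replicated here, and the Gaussian least-squares realization is more
permissive toward the equal-parameter concave candidates (log, root).
On finite fGn windows ($N = 256$, 25 grid points) it selects the linear
model only ~20–30% of the time, with winners spread across log/root and
higher polynomials and a median AIC margin of ~2.6 — real finite-size
concavity, not a tie-break artifact. The stage is therefore exercised on
its discriminative contract (exact power law → linear wins with slope
recovered to $10^{-6}$; constructed two-slope crossover → a nonlinear
candidate wins), and aggregate linear-selection percentages on noisy
windows should not be compared against rates produced by the original
likelihood.

A related caveat holds for stage 2: an outright ARFIMA majority is only
observed when the data really follow an ARFIMA law (~64% preference on
ARFIMA(0, 0.3, 0) windows). On fGn — a different long-memory process —
the plug-in $d = \hat H - 0.5$ leaves small AIC margins (~47%
preference at $H = 0.75$), still far above the ~10% observed for
short-memory AR(1) input, which is the contrast that matters for the
cascade's discriminative role.

## Group statistics and classification

Per-window task-vs-rest differences use a two-sided Mann–Whitney U test
by default (`test = "auto"` gates a t-test on a Lilliefors-style KS
normality screen of both samples); the "significant period" is the
longest contiguous run of $p < 0.05$, uncorrected — mirroring per-window
reporting conventions — with optional Benjamini–Hochberg via `p_adjust`.

Classification uses the *smoothed* $\hat H_{BB}$ from C3, Cz, C4 as three
features in a pooled-covariance LDA (shrinkage toward the diagonal only
on singularity). Within-subject: per window, rest trials are randomly
subsampled to match the task count (redrawn each repetition, seeded) and
10×10-fold stratified CV yields accuracy and F1 (task = positive class).
Across subjects: leave-one-participant-out. Chance level is the exact
binomial bound: smallest $k$ with
$P(X \ge k \mid \mathrm{Bin}(n, 0.5)) \le 0.05$, e.g. 65.0% at $n = 40$.
On null data, cross-validated LDA accuracy sits slightly *below* 50% on
average (the held-out fold's class means oppose the training direction);
this is expected and covered by the null-calibration tests.

## The synthetic world

`gen_dataset()` emulates two paradigms: asynchronous single taps (6 s
trials, −3..+3 s around onset, 40 trials/condition) and cued continuous
tasks (7 s trials, −3..+4 s, 22 trials). Each channel sums:

* broadband fGn (exact circulant embedding — exact covariance, so the
  generator doubles as an oracle) whose $H$ cross-fades from
  `H_rest = 0.60` to `H_move = 0.75` over the task interval
  (raised-cosine ramps, 0.5 s default);
* a 10 Hz carrier with a strictly positive envelope built from smoothed
  fGn through a softplus (quasi-affine, so the envelope keeps its
  prescribed exponent on analysis timescales), whose envelope $H$ drops
  from 0.80 to 0.65 during the task — the coupled opposite modulation;
* white measurement noise (SD 0.1 relative to unit-variance fGn).

Defaults were chosen once: $\Delta H = 0.15$ is the effect size the
acceptance suite prescribes; envelope exponents bracket commonly reported
resting alpha-envelope values; `alpha_amp = 0.5` keeps the oscillation
visible without letting the 10 Hz peak dominate the broadband estimate.
Channels are i.i.d. (no spatial structure); there are no artifacts, no
1/f background beyond what fGn implies, and no genuine nonstationary-$H$
process — the cross-fade of stationary segments *is* the model, and the
recorded ground truth is the blended profile. A green end-to-end test
therefore establishes that the pipeline recovers known Hurst dynamics
from a clean additive world, not that it handles ocular artifacts, volume
conduction, or participant variability.

Within a trial the $H$-rest and $H$-move fGn components are generated
independently (per the cross-faded-blocks design); across the fade this
superposes two incoherent processes, which mildly flattens $\hat H$ inside
the ramp relative to the blended ground truth — visible as a slightly
delayed rise, not a qualitative artifact.

**Timing of the task modulation.** The default `task_start` is −0.5 s for
the asynchronous paradigm (elevation beginning during late movement
intention, ramp onset −1.0 s) and 0 s for cued trials. Because features
are causal ($[t-2, t]$), a classifier can only cross the chance threshold
*before* the event if elevated $H$ already occupies a substantial part of
the pre-event window. The prediction-lead acceptance test therefore uses
an intention-like world with `task_start = -1.5` (elevation from −2.0 s,
the readiness-potential timescale), which is the premise of that
criterion — a ramp confined to the last 0.5 s before onset does not put
enough pre-onset signal into any causal window to clear an exact binomial
threshold, regardless of implementation.

## Reproducibility

Every randomized step draws from an explicit seed; per-trial sub-seeds
derive deterministically from the dataset seed. `run_pipeline()` persists
all intermediates plus a JSON manifest (config, seed, package version);
rerunning with the same manifest reproduces byte-identical CSVs. The EDF
writer emits plain 16-bit EDF (one record per trial) with events in a
JSON sidecar; EDF+ annotations are out of scope.
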