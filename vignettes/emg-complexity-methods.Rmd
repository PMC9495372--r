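---
title: "Methods: complexity analysis of surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity analysis of surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgcomplexity)
```

## Scope and model of the data

This package analyzes surface EMG recorded during 5 s isometric
contractions sampled at 1000 Hz, in a fully within-subject design:
each subject is measured under two stretching conditions (static,
neurodynamic) at three time points (BASELINE, WARM, STRETCH), with
maximal and submaximal (40 % of maximal torque) contractions. The
scientific question the tooling serves is whether nonlinear
"complexity" measures of the EMG — sample entropy, recurrence
structure, fractal scaling — detect neuromuscular changes that the
classical RMS amplitude does not.

The unit of analysis is a 1 s window: centered on the maximal
voluntary torque peak for maximal contractions (0.5 s on each side),
and seconds 3–4 of the plateau for submaximal ones. Windows this
short trade estimator variance for stationarity; the choice mirrors
common practice in the fatigue literature and is kept fixed here.

## Preprocessing

EMG is band-pass filtered at 20–300 Hz with a Butterworth filter of
total order 4 (two poles per band edge), applied forward and backward
(`signal::filtfilt`) so windows suffer no phase distortion. Zero-phase
application doubles the effective roll-off; since the same filter is
applied to every trial this affects all cells of the design equally.
Published descriptions of such pipelines rarely state phase handling
or whether "4th order" counts the transfer function or the prototype
low-pass; we fix the transfer-function order and document it.

Two ordering decisions are contracts of the pipeline:

- the filter is applied to the *full* trial, and windows are cut from
  the filtered signal (filtering a short window would waste samples on
  edge transients);
- all complexity measures consume the *same* filtered window that the
  RMS uses, so every measure describes one signal.

The sliding RMS uses a centered 250 ms window and a truncated output —
no padding, one value per fully admissible position — because padding
fabricates data at the edges. The maximal-torque peak is located
automatically: the torque trace is smoothed with a zero-phase 10 Hz
low-pass, the smoothed argmax taken (exact ties resolve to the
earliest sample), and the reported peak is the raw maximum within
±50 ms. If the peak sits closer than 0.5 s to a trial edge the window
clamps to the trial bounds with a warning.

## Sample entropy

SampEn(m, r) = −ln(A/B) with m = 2 and r = 0.2 × SD of the window,
Chebyshev distance, matches scored at distance ≤ r, self-matches
excluded. Both the m and m + 1 counts run over the same
N − m·delay templates, so A/B is a proper conditional probability.
The embedding delay defaults to 1. Because r tracks the sample SD,
SampEn is exactly invariant to affine transforms of the signal. A
constant window (r = 0) is a degenerate input and raises an error; a
window with no m + 1 matches returns +Inf with a flag rather than a
silent number. Conventions differ across published implementations in
whether N − m or N − m − 1 templates are used; the package fixes
the former and its test oracle enforces exact agreement by explicit
template counting.

## Recurrence quantification

The window is embedded with delay τ = 5 and dimension d = 10 (the
fixed analysis parameters; average-mutual-information and
false-nearest-neighbor estimators are provided as utilities for
checking those choices, with their heuristics — Sturges-rule
histogram bins for AMI, Kennel tolerances 10 and 2 with a 1 %
threshold for FNN — labeled approximate). Euclidean distances
between embedded states are normalized by the *maximum* pairwise
distance, which makes %Rec and %Det invariant to affine transforms
of the signal; a recurrence is a normalized distance strictly below
0.25. The line of identity is excluded from both numerator and
denominator (Theiler window 1), since self-recurrences are trivial.
%Det counts recurrent points on diagonal segments of length ≥ 3.
Diagonals are scanned on the upper triangle and doubled, which is
exact by symmetry. A constant window makes the normalization
degenerate; it is flagged, and reported as 100 % recurrence and
determinism (every state recurs identically and every diagonal is
unbroken).

## Detrended fluctuation analysis

The profile is the cumulative sum of the *mean-subtracted* window —
without mean subtraction the slope is dominated by the mean trend.
The profile is cut into non-overlapping boxes anchored at the series
start, remainder discarded; a least-squares line is removed per box
(first-order detrending only); F(n) is the RMS of the residuals over
retained samples; and α is the OLS slope of log₁₀ F against log₁₀ n
over 40 log-spaced integer box sizes from 4 to 251 (deduplicated
after rounding, so typically 39 distinct sizes). Some DFA variants
average forward and backward box anchorings; we use a single
anchoring, matching the plain "non-overlapping boxes" description.
The log base cancels in the slope.

With a 1000-sample window the largest box (251) leaves only 3 boxes,
so F(251) is a high-variance estimate; it is reproduced as specified,
and the calibration tests therefore average over 20 independent
realizations. On synthesized noise the estimator recovers
α = 0.5/1.0/1.5 for white/pink/brown inputs within the ±0.1
calibration tolerance (acceptance suite), and the summation-shift
property α(cumsum x) ≈ α(x) + 1 holds within ±0.1.

## Statistical layer

Each variable is analyzed with a two-way fully within-subject ANOVA
(condition × time); each effect is tested against its own
subject-by-effect interaction error term (`stats::aov` with Error
strata). Sphericity is evaluated per effect with Mauchly's test on
the covariance of orthonormal contrast scores (marginal means over
the other factor for main effects, Kronecker-product contrasts for
the interaction); the two-level condition factor is trivially
spherical (ε = 1). When Mauchly rejects at α = 0.05 the
Greenhouse–Geisser ε rescales both degrees of freedom of that
effect's F test — the correction is conditional, not unconditional.
Partial η² = F·df1/(F·df1 + df2), identical to
SS_eff/(SS_eff + SS_err).

Post hoc comparisons are paired t tests on marginal means (averaged
over the other factor, matching the convention of reporting a single
time post hoc across conditions), with Bonferroni adjustment
min(1, p × n_pairs) and unadjusted 95 % CIs from the paired-t
distribution. Cohen's d defaults to mean difference / SD of the
paired differences; because published reports often leave the d
formula unstated, a pooled-SD alternative is available via
`d_method = "pooled"`. Descriptors: |d| < 0.5 small, 0.5–1.2 medium,
> 1.2 large.

## Synthetic data: what it emulates and what it does not

`gen_colored_noise()` synthesizes Gaussian-type series in the
frequency domain — amplitudes ∝ f^(−β/2), uniform random phases,
Hermitian symmetry — giving exact control of the spectral exponent,
unlike autoregressive approximations. `gen_emg_trial()` builds a
trapezoidal torque profile (0.5 s ramps, central 4 s plateau, so the
analysis windows always exist; smooth 10 Hz jitter of 1 N·m RMS) and
EMG channels as band-limited (20–300 Hz) noise amplitude-modulated by
the normalized torque envelope, plus a broadband noise floor. Default
amplitudes (0.01 mV per N·m of plateau torque, 0.02 mV noise floor,
100 N·m maximal plateau, between-subject torque SD 15 N·m) were
chosen once for a plausible signal-to-noise ratio of surface EMG over
hamstring muscles; no published distributional description of such
raw signals exists to calibrate against.

The surrogate contains no motor-unit-level structure, no fatigue
dynamics and no cross-talk; its in-band spectral tilt
(`carrier_exponent`, default 0.5 between white and pink) is the only
"physiological" degree of freedom. Consequently, passing tests show
that the *estimators and statistics* behave correctly on signals of
known structure — they do not validate physiological claims about
real EMG.

`gen_cohort()` produces the full balanced design. Injected effects
work at two levels: the ground-truth table carries exact additive
shifts (in between-subject SD units) for any variable, which is what
the power and type-I-error calibrations use; at the signal level,
torque shifts move the plateau and `sampen` shifts whiten the EMG
carrier (raising measured entropy, lowering α). An exact "+1 SD of
SampEn" cannot be identified through the signal chain, so
signal-level recovery tests assert direction and significance rather
than magnitude. `simulate_cohort_table()` bypasses signal synthesis
entirely for statistical calibration: 500 null replicates put the
GG-corrected time-effect type-I error at 5 % ± 2 %, and a shift
calibrated to paired d = 1.0 (shift = √2 × within-SD on cell values,
i.e. 1 × the SD of marginal-mean differences) is detected in well
over 80 % of replicates at n = 16.

All randomness is seeded: every generator takes a `seed`, restores
the global RNG state (`withr::with_seed`), and cohort generation
derives per-trial sub-seeds deterministically from the cohort seed,
so fixed seeds give bit-identical output.

## Numerical choices and degenerate inputs

- Strict "<" for the recurrence threshold, closed "≤" for the SampEn
  tolerance — each the standard convention for its measure.
- DFA drops box sizes above N/2 and any scale with exactly zero
  fluctuation, with warnings; fewer than two usable scales is an
  error (a slope needs two points).
- Constant inputs: error for SampEn and DFA (both are undefined),
  flagged degenerate for RQA, warning plus mid-signal index for the
  torque peak finder.
- The false-nearest-neighbor ratio criterion floors its denominator
  at √ε × SD so exactly recurring states (distances at floating-point
  noise level) are not spuriously flagged.
- Problem sizes in the test and calibration suites — 20 realizations
  of n = 4096 for noise calibration, series up to n = 2000 (SampEn)
  and n = 300 (RQA) for oracle equivalence, 500 null cohorts for
  type-I calibration, one 16-subject cohort (192 trials) end to end —
  were chosen as the smallest sizes at which the stochastic
  quantities are stable at the stated tolerances.

## Known limitations

- The RM-ANOVA layer requires a complete balanced design and refuses
  missing cells rather than imputing; real studies with dropouts need
  mixed models, which are out of scope.
- Multiscale entropy and multifractal DFA are deliberately not
  implemented.
- The recurrence matrix is dense (O(n²) memory); fine for 1 s windows
  (~955 embedded states) but not for minutes-long recordings.
- Units: torque is treated as N·m and EMG as mV throughout; nothing
  in the math depends on the units, only the labels.
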