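---
title: "Phase-binned analysis of oscillatory entrainment of visual detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-binned analysis of oscillatory entrainment of visual detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavosc)
```

## The experimental paradigm

A peripheral disc flickers sinusoidally in luminance at a fixed frequency
(5 Hz, ~9.6 Hz — a typical individual alpha frequency — or 15 Hz) while an
observer fixates centrally and reports near-threshold target flashes at
several positions. Each 6.25 s trial contains 2–4 single-frame targets
(probabilities 0.5 / 0.375 / 0.125), scheduled at random times that avoid
the first and last 800 ms of the trial and keep at least 800 ms between
targets. Target luminance is adapted per position by a staircase so that
detection stays near 50%. Positions follow cortical magnification
(eccentricities 5.4 / 2.9 / 1.5 degrees in the 9-position layout; the
5-position layout spans 5.4–2.9 degrees logarithmically); exactly one
position sits next to the disc.

The scientific question is *where and with what phase* the entrained
oscillation modulates detection: binning each target by the oscillation
phase at its onset and fitting the per-bin hit rates with a cosine yields a
modulation amplitude and a preferred phase per position, and the spatial
pattern of those two quantities separates a *local* entrainment component
(at the position adjacent to the disc) from a *global* one (a common phase
shared by distant positions).

## Conventions and fixed geometry

* **Phase convention.** Phase 0 is the luminance minimum (black) and phase
  ±π the maximum (white): `L(phi) = 255 (1 - cos phi) / 2` on an abstract
  0–255 scale. This convention is forced by the luminance-flash control,
  whose unmeasurable bin — a black disc on the black background — sits at
  phase zero. No display calibration (gamma, cd/m²) is modelled.
* **Binning.** `K = 8` equally spaced half-open bins with centers
  `-pi, -3pi/4, …, 3pi/4`. A phase exactly on a boundary belongs to the
  upper bin (a tie rule the original description leaves open, fixed here
  as a documented constant); the region within half a bin of +π wraps onto
  the −π bin.
* **SOA map.** The masking control probes signed SOAs
  ±50, 37.5, 25, 12.5, 0 ms, mapped linearly onto one 100 ms cycle
  (`phi = 2 pi soa / period`). The two ±50 ms endpoints denote the same
  point of the cycle and are merged into the single −π bin before fitting.
  (One printed occurrence of "12.25 ms" in the source material is treated
  as a typo for 12.5 ms, the value consistent with the π/4 phase step.)
* **Quantized luminance levels.** The display levels {64, 128, 192, 255}
  used by the luminance-flash control are the hardware's rounding of
  `L(phi)` at the bin centers; the simulator uses the continuous sinusoid,
  while the control analysis uses the exact published level↔bin assignment
  (255, 192, 128, 64, 64, 64, 128, 192 for bins −π…3π/4), including the
  level-192-at-±3π/4 convention even though the continuous curve gives
  ≈218 there.

## The synthetic observer

`observer_model()` is the generative stand-in for a human observer:

```
p(detect) = guess + (1 - guess - lapse) * logistic(slope (log L - log theta))
            * (1 + (m/2) cos(phi - phi_pref))
```

clipped to [0, 1]. The cosine gain multiplies the psychometric term only,
so `m` is interpretable as the relative peak-to-trough modulation of
detection probability at threshold; guesses and lapses are not
phase-modulated. Defaults, chosen once as study-scale values:

| parameter | default | why |
|---|---|---|
| `threshold` | 100 (0–255 scale) | mid-range luminance, leaves staircase headroom |
| `slope` | 8 per log-luminance unit | a steep but ordinary psychometric slope |
| `guess_rate` | 0 | the task analyses hits only; no false-alarm model |
| `lapse_rate` | 0.02 | typical attentive-observer lapse rate |
| `local_phase`, `global_phase` | +π/4, −π/4 | a quarter-cycle local/global separation — "a fraction of a cycle", as observed; absolute phases are not published, only differences matter |
| `modulation_depth` (exp-2 profile) | 0.52, 0.45, 0.43, 0.40, 0.40 | at the 50% staircase baseline these give ~22% mean absolute peak-to-trough with an ~18% drop from position I to II, the published scale |

The staircase is multiplicative 1-up/1-down with step 1.1 starting at
luminance 150: a hit divides luminance by the step, a miss multiplies it
(capped at 255). Its equilibrium is the 50% point of the full psychometric
function, matching the stated design goal; the algorithm itself is not
specified in the source material, so this standard choice is ours. No
burn-in is excluded anywhere, matching the original analysis which excludes
nothing.

Trial schedules are sampled *uniformly* over the feasible set of onset
times (margins + minimum gaps) by the ordered-gap construction: subtracting
the mandatory gaps maps constrained ordered onsets onto order statistics of
i.i.d. uniforms. The disc's phase at trial start is uniform, so onset
phases cover the cycle without favouring any bin.

What the generator deliberately does **not** emulate: reaction times and
false alarms, eye movements and saccadic suppression, masking dynamics,
attention fluctuations, learning/fatigue drifts, and between-subject
heterogeneity of preferred phase beyond the local/global split. Passing
tests therefore certify the statistical machinery under the stated
generative model, not the full richness of human data.

## The analysis chain

**Cosine fit.** `fit_cosine()` minimises unweighted least squares of
`b + A cos(phi - phi0)` over the bin-mean hit rates, solved by the shared
normal equations (for K ≥ 3 equally spaced full-coverage bins this is the
first-harmonic Fourier projection; tests verify equality with a brute-force
phase-grid search at 10⁻³ rad). The fit is unweighted — mirroring the
original procedure — which is innocuous because the design balances trial
counts across bins. Numerical choices: amplitudes below 10⁻¹² are snapped
to zero (they are pure round-off) and flat fits report phase 0 with a
`degenerate` flag so phase tests can refuse them; empty bins are dropped
with a warning provided at least as many usable bins remain as
identifiable parameters (with K = 2 the sine regressor is collinear and is
dropped, so two bins identify two parameters and the amplitude becomes
half the rate difference between the bins).

**Group averaging.** The fixed-effect group curve is the unweighted mean of
subject rates per bin (subjects empty in a bin are skipped in that bin);
per-bin counts are summed because the surrogate construction needs them.

**Amplitude Monte Carlo.** Under the null that performance is equal across
bins, each subject's trials are redrawn Bernoulli with that subject's
pooled hit rate, preserving per-bin counts exactly; surrogates are averaged
across subjects and refitted with the *same* fitting code path as the
observed data. `p` is the raw proportion of surrogate amplitudes ≥
observed (it can be exactly 0, as in the original definition); the
conservative `(r+1)/(n+1)` bound is reported alongside. The reference
surrogate count is 50,000; the demo profile uses 2,000.

**Phase-difference Monte Carlo.** The null keeps both locations oscillating
with a *common* preferred phase: surrogate pairs use each location's
per-bin summed counts with per-bin rates equal to the two-location average.
The statistic is the absolute circular distance in [0, π] (the principal
value; multi-cycle ambiguity is an interpretive matter addressed
experimentally by denser spatial sampling, not by the test).

**Multiple comparisons.** "FDR" is implemented as Benjamini–Hochberg
(step-up), applied across positions for amplitude tests and across pairs
for phase tests, within one experiment — the scope the methods describe;
correction across experiments is not applied.

**Cross-condition statistics.** Fitted amplitudes enter a balanced two-way
fixed-effects ANOVA (frequency × position) with Welch post-hoc t-tests
(BH-corrected); phase-difference profiles are compared across frequencies
with a Watson–Williams F test (implemented from the standard formulae with
the 1 + 3/(8κ) correction and Fisher's A1-inverse estimate of κ, validated
against a label-permutation oracle; a warning fires when the within-group
resultant length drops below 0.45). The subject-selection check is a plain
Pearson 2×2 chi-square without continuity correction — the published bound
holds either way (χ² ≈ 21.1 uncorrected, ≈ 17.3 with Yates).

**Reported amplitude paths.** Published amplitudes could be read either as
fits of the subject-averaged curve or as averages of per-subject fits; both
are provided (`amplitude_tests_by_position()` reports the group-curve fit,
`fit_table()` the per-subject fits), and significance always uses the
group (fixed-effect) path, as the methods specify.

## Problem sizes and calibration

The test suite exercises the machinery at sizes chosen to make the checks
sharp yet quick: calibration of the amplitude test uses 500 replicate
zero-modulation experiments (2 subjects, one position, 20 targets per cell)
at 1,000 surrogates each; the phase-difference test is calibrated on 500
common-phase replicates and its power measured on 100 quarter-cycle-offset
replicates at 200 targets per bin; full-scale recovery uses 15 subjects,
5 positions and ~33 targets per phase×position cell — the published cell
occupancy — at 2,000 surrogates. Oracle equivalence of the cosine fit is
checked on 1,000 random curves. The pipeline demo runs 3 subjects at 2,000
surrogates so that an end-to-end run stays in the seconds range.

A note on calibration: because the staircase feeds outcomes back into
luminance, total hits per run are stabilised below binomial variance, and
the i.i.d.-Bernoulli surrogates are then very slightly conservative for
staircase data (empirically ~4.5–5% rejections at nominal 5%). This is a
property of the original surrogate scheme itself, shared by any analysis of
staircase-controlled data with exchangeable-bin surrogates.

## Known limitations

* Fixed-effect inference only: the Monte Carlo tests compare grand averages
  to surrogate grand averages and do not model between-subject variance
  (no mixed-effects path, by design).
* Only the first harmonic is fitted; genuinely non-sinusoidal modulation is
  summarised by its fundamental.
* The raw-proportion p-value can be exactly zero; for downstream use where
  zero is awkward, the conservative bound is also returned.
* The luminance-flash control restricts fitted phases to {0, π} by
  construction (the package reports π as −π under its [−π, π) convention),
  so no phase analysis is meaningful there.
* The synthetic observer is a single-mechanism model; it is a tool for
  validating the analysis, not a model of visual cortex.
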