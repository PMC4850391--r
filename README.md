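# behavosc

Analysis of **behavioural oscillations**: psychophysics experiments in which
a peripheral disc, flickering sinusoidally in luminance, entrains visual
detection performance across the visual field. Observers fixate centrally
while near-threshold targets are flashed at several positions and random
times; expressing hit rate as a function of the oscillation phase at target
onset reveals a "preferred phase" at which detection is best, and the
preferred phase near the entraining disc can differ from the common phase
shared by distant positions (a *local* versus a *global* entrainment
component).

The package is aimed at psychophysicists who want to run this analysis chain
on trial tables of their own, and at methodologists who want to study its
statistical behaviour on fully synthetic observers.

## What it computes

For each subject and target position, targets are assigned to one of `K = 8`
phase bins of the entraining cycle and the per-bin hit rate `h_k` is fitted
with a three-parameter cosine

```
h(phi) = b + A * cos(phi - phi0)
```

(baseline `b`, half-amplitude `A`, preferred phase `phi0`), by unweighted
least squares over the bin means — for equally spaced full-coverage bins this
is the first-harmonic Fourier projection. The reported modulation
"amplitude" is the peak-to-trough difference `2A`.

Significance is assessed with the original Monte Carlo surrogate scheme:

* **Amplitude test** — surrogate datasets redraw every trial's outcome as
  Bernoulli with the subject's pooled across-bin hit rate (per-bin trial
  counts preserved), average across subjects, and refit; `p` is the
  proportion of surrogate amplitudes `>=` the observed one (fixed-effect,
  grand-average statistic).
* **Phase-difference test** — for two positions, surrogates share a common
  per-bin rate (the two-position average) and the statistic is the absolute
  circular distance between fitted preferred phases.
* p-values are FDR-corrected (Benjamini–Hochberg) across positions or pairs.

Around this core: a synthetic observer (logistic psychometric function in
log-luminance, multiplicative cosine gain, 1-up/1-down staircase, the exact
trial scheduling rules), a two-way frequency × position ANOVA on fitted
amplitudes with post-hoc t-tests, a Watson–Williams test for circular means,
a 2×2 chi-square for subject selection, and the two control analyses
(SOA-masking control; luminance-flash control rearranged onto an emulated
phase cycle).

## Worked example

Simulate 15 observers at the individual-alpha-like frequency (9.6 Hz) with
the 5-position layout and the study-scale modulation profile, then test every
position and the adjacent-vs-neighbour phase difference:

```r
library(behavosc)
config   <- experiment_config(n_surrogates = 2000)
observer <- observer_exp2()
datasets <- simulate_experiment(config, observer, n_subjects = 15,
                                targets_per_cell = 33, seed = 1)
amplitude_tests_by_position(datasets, config, seed = 2)
#>   position_id peak_to_trough preferred_phase p_raw p_adj significant
#> 1           I          0.250           0.744     0     0        TRUE
#> 2          II          0.228          -0.730     0     0        TRUE
#> 3         III          0.214          -0.845     0     0        TRUE
#> 4          IV          0.204          -0.593     0     0        TRUE
#> 5           V          0.206          -0.874     0     0        TRUE

phase_difference_tests(datasets, config,
                       pairs = list(c("I", "II"), c("II", "III")), seed = 3)
#>   position_a position_b phase_difference p_raw p_adj significant
#> 1          I         II            1.474 0.000 0.000        TRUE
#> 2         II        III            0.115 0.421 0.421       FALSE
```

Every position shows a significant oscillatory modulation (mean
peak-to-trough 22% of performance, i.e. hit rate swings ~11 percentage
points either side of the ~50% staircase baseline). Position I — the one
adjacent to the flickering disc — has a preferred phase ~1.5 rad away from
its neighbour (the injected local/global separation is π/2), while the
distant positions II and III share a common phase (p = 0.42).

The same chain runs from a YAML config and writes tables, a report and a
run manifest:

```sh
Rscript inst/scripts/behavosc all --config inst/extdata/demo_config.yaml --outdir out/
```

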