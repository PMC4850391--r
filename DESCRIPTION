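Package: behavosc
Title: Phase-Binned Analysis of Oscillatory Entrainment of Visual Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing behavioural oscillations in visual detection
    experiments in which a peripheral luminance oscillation entrains detection
    performance across the visual field. Provides a synthetic-observer
    generator emulating the trial structure of such experiments (near-threshold
    targets scheduled inside 6.25 s trials, a 1-up/1-down luminance staircase,
    and cosine phase modulation of detection probability with distinct local
    and global preferred phases), phase-binned hit rates with three-parameter
    cosine fits, Monte Carlo surrogate tests for oscillatory amplitude and for
    preferred-phase differences with false-discovery-rate correction, circular
    Watson-Williams comparisons, fixed-effect ANOVA on fitted amplitudes, and
    two control analyses (stimulus-onset-asynchrony masking control and
    luminance-to-phase-bin rearrangement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
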