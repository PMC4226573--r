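Package: pulsedecomp
Title: Gaussian Decomposition of Radial Artery Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes radial artery pressure waveform (RAPW) beats into
    three positive Gaussian sub-waves with a two-stage particle swarm
    optimizer, and derives wave-reflection indices from the forward
    (first) and reflected (second) components. Provides the full analysis
    pipeline: synthesis of ECG + RAPW pulse trains and of subject-level
    index cohorts, baseline-wander removal, R-peak and pulse-foot
    detection, ectopic-beat exclusion, beat segmentation, width and
    amplitude normalization to a canonical 1000-sample unit-amplitude
    episode, constrained Gaussian curve fitting, per-subject index
    averaging, blood-pressure summaries, and two-way (sex x SBP category)
    analysis of variance on unbalanced cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
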