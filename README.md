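# pulsedecomp

Gaussian decomposition of radial artery pressure waveforms (RAPW) for
quantifying arterial wave reflection, with the statistics to test how
reflection changes with blood pressure and sex.

An early return of the reflected pressure wave is a recognized
cardiovascular risk marker. Rather than locating fiducial points on the
raw pulse — notoriously sensitive to noise and convention — this package
decomposes each normalized beat into three positive Gaussian sub-waves,

    f(n, x) = Σ_k  H_k · exp( −(n − C_k)² / (2 W_k²) ),   k = 1, 2, 3,

on the canonical axis n = 1..1000, with peak heights H_k, half-widths
W_k and ordered peak positions 1 < C1 < C2 < C3 < 1000. The first
sub-wave represents the forward (ejection) wave, the second the main
reflected wave. Reflection is summarized per subject by the peak
position interval **C_ref-forw = C2 − C1** and the peak height ratio
**H_ref/forw = 100·H2/H1 (%)**, averaged over ten consecutive clean
beats. The nine-parameter least-squares fit is solved by a two-stage
particle swarm optimizer with an optional Levenberg–Marquardt polish.

The package is self-contained for testing: it synthesizes two-channel
ECG + RAPW pulse trains with known ground truth, and subject-level
cohorts (190 subjects in sex × SBP-category cells) for the two-way
ANOVA stage. It is aimed at researchers in pulse-wave analysis and at
anyone needing a tested, reproducible reference implementation of
Gaussian pulse decomposition.

## Worked example

Simulate a recording, preprocess it, fit ten beats, and compute the
subject's reflection indices:

```r
library(pulsedecomp)

gt  <- pulse_ground_truth()                       # physiologic beat shape
tr  <- generate_pulse_train(gt, train_spec(n_beats = 13, seed = 42))
ann <- annotate_record(tr)                        # baseline, R-peaks, feet, ectopy
sel <- segment_and_select(ann$rapw, ann$beat_annotations$foot,
                          ann$beat_annotations$ectopic, k = 10)
norm <- lapply(sel$episodes, normalize_episode)   # 1000 samples, range [0, 1]
fits <- fit_episode_batch(norm, fit_config(seed = 42))

fits[[1]]
#> pulse_fit: SSE 0.0559 (RMSE 0.007476), 14120 evaluations, converged: TRUE
#> Gaussian triplet (H = height, W = half-width, C = position)
#>   forward reflected diastolic
#> H   0.563     0.650     0.256
#> W  52.437    96.793   169.955
#> C 145.857   245.724   605.823

compute_indices(fits)
#>      C1    C2     H1     H2 C_ref_forw H_ref_forw n_episodes
#> 1 143.7 252.9 0.6449 0.6115      109.2      94.82         10
```

The fitted residual (RMSE ≈ 0.0075) sits at the injected noise floor.
`C_ref_forw = 109.2` says the reflected peak trails the forward peak by
about 11% of the cardiac cycle; `H_ref_forw = 94.8%` says the two waves
have nearly equal amplitude on the normalized beat.

Cohort-level inference — does reflection timing change with blood
pressure, with sex, or their interaction?

```r
coh <- generate_cohort(reference_cohort_spec(seed = 42))   # 190 subjects
two_way_anova(coh, "C_ref_forw")
#>             effect     F df1 df2        p bucket significant
#> 1              sex  2.75   1 182 9.91e-02     NS       FALSE
#> 2     sbp_category 18.88   3 182 1.05e-10 P<0.01        TRUE
#> 3 sex:sbp_category  1.08   3 182 3.59e-01     NS       FALSE
```

The SBP-category main effect is strong (reflection returns earlier at
higher pressure) while sex and the interaction are not significant —
the expected pattern under the bundled reference parameterization.

A thin CLI over the same functions lives in `inst/cli/pulsedecomp.R`
(subcommands `simulate`, `preprocess`, `normalize`, `fit`, `indices`,
`anova`, `run-all`).

## Package layout

* `R/synthetic.R`, `R/cohort.R` — beat-train and cohort generators
* `R/preprocess.R` — baseline removal, R-peak/foot detection, ectopy,
  segmentation
* `R/normalize.R` — width and amplitude normalization
* `R/model.R`, `R/fit.R` — the three-Gaussian model, objective and
  TSPSO fitter
* `R/indices.R`, `R/anova.R` — reflection indices, pressures, two-way
  ANOVA, group summaries
* `R/pipeline.R` — end-to-end orchestration with CSV/JSON artifacts
* `vignettes/pulse-decomposition-methods.Rmd` — model, assumptions,
  design choices and limitations
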