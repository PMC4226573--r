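---
title: "Methods: Gaussian decomposition of radial pulse waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian decomposition of radial pulse waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedecomp)
```

## The model

A radial artery pressure waveform (RAPW) beat, once mapped to the
canonical axis `n = 1, ..., 1000` with unit amplitude range, is modeled
as the sum of three positive Gaussian sub-waves

$$ f(n, x) = \sum_{k=1}^{3} H_k \exp\!\left( -\frac{(n - C_k)^2}{2 W_k^2} \right), $$

with peak heights $H_k > 0$, half-widths $W_k > 0$ (the Gaussian width
scale, in canonical samples) and peak positions constrained to
$1 < C_1 < C_2 < C_3 < 1000$. The first sub-wave is read as the forward
(left-ventricular ejection) component, the second as the main reflected
component returning from the periphery, and the third as the late
diastolic component. The fit minimizes the sum of squared errors

$$ J(x) = \sum_{n=1}^{1000} \left( S(n) - f(n, x) \right)^2 $$

over the nine parameters, where $S(n)$ is the normalized pulse.

Wave reflection is quantified per subject by averaging $C_1, C_2, H_1,
H_2$ over ten consecutive artifact-free beats and deriving the peak
position interval $C_{ref-forw} = C_2 - C_1$ (reflection timing, as a
fraction of the cardiac cycle times 1000) and the peak height ratio
$H_{ref/forw} = 100 \cdot H_2 / H_1$ (reflection amplitude, percent).
The ratio is computed from the averaged heights (ratio of means), not
as a mean of per-beat ratios; the bundled reference table is numerically
consistent with this order of operations (e.g. $0.77/0.61 \to 126$).

All indices live on the normalized 1000-sample axis — dimensionless
fractions of the beat — not in milliseconds, because width
normalization removes the beat-duration scale.

## Pipeline and its assumptions

1. **Baseline removal** (0–0.05 Hz). The slow band is estimated by
   block-mean decimation (to roughly 5 Hz) followed by a least-squares
   projection onto the subspace spanned by Fourier components at and
   below the cutoff plus a cubic trend, and subtracted. The subtracted
   component lies in the 0–0.05 Hz subspace by construction, so beat
   morphology cannot be phase-distorted. A conventional forward–backward
   IIR high-pass at this cutoff is numerically fragile at 1000 Hz
   (normalized cutoff 1e-4); the projection is exact for constants and
   attenuates a 0.02 Hz unit sinusoid to below 0.03. Its passband is
   exact except within roughly `1/cutoff` (20 s) of the record edges,
   where slow components are estimated one-sidedly; beats there may see
   a small additive slow offset, which the per-beat amplitude
   normalization absorbs.

2. **R-peak detection.** Zero-phase difference-of-moving-averages
   band-pass emphasis, a threshold relative to the 99.5th percentile of
   the emphasized amplitude (making detection scale-invariant), a
   0.25 s refractory period, and refinement to the raw local maximum.
   This is a deliberately simple timing-anchor detector: R-peaks only
   anchor the beat search windows.

3. **Pulse-foot detection.** The onset is modeled as a change point
   between late-diastolic decay and the systolic upstroke: a coarse
   minimum of the smoothed pressure inside the post-R window is refined
   by maximizing a two-line likelihood-ratio score (single-line SSE
   minus split SSE over ±20-sample windows). Detected R-to-foot delays
   are then regularized record-wide: pulse transit time is nearly
   constant within a recording, so feet deviating more than 10 ms from
   the record's median delay are replaced by the median-delay
   prediction. The classical intersecting-tangent construction was
   evaluated and rejected for this model class: on beats whose onset is
   a Gaussian rise from near zero, the tangent intersection lands near
   $C_1 - 2 W_1$ canonical samples from the true onset — a
   shape-dependent bias of tens of samples.

   Localization accuracy is bounded by the beat model itself: a sum of
   Gaussians is $C^\infty$, so the segmentation junction carries only a
   small slope discontinuity (~1e-3 amplitude/sample under default
   conditions). Noiseless trains are localized within ±5 samples;
   at noise SD 0.02 the median error stays within ±5 but worst-case
   beats can err by ~10–15 samples — an estimation-theoretic limit, not
   a detector defect. A *consistent* foot bias cancels in
   $C_{ref-forw}$ and leaves $H$ indices untouched, so the reflection
   indices are robust to it.

4. **Ectopic exclusion.** A beat interval deviating more than 20% from
   the 7-beat running median RR flags both bounding beats. Threshold
   and window are configuration keys; this is an operational stand-in
   for dedicated ectopy classifiers, sufficient to exercise the
   exclusion rule.

5. **Segmentation and selection.** Beats are half-open sample ranges
   `[foot_i, foot_{i+1})` (0-based indices throughout); the earliest
   run of ten consecutive clean beats is selected. Ten beats span at
   least one respiratory cycle at typical rates, so respiratory
   amplitude variation is averaged rather than aliased.

6. **Normalization.** Width first (linear interpolation onto 1000
   uniformly spaced points spanning the episode; cubic available), then
   min–max amplitude scaling to [0, 1]. Linear interpolation is the
   minimal assumption and preserves monotone rising edges. The two
   operations commute only up to interpolation accuracy (resampling
   moves interpolated extrema by O(step²)·curvature, ~1e-7 here).

## The two-stage swarm optimizer

Stage 1 runs a global PSO (default: 40 particles, 150 iterations,
inertia 0.9 → 0.4 linear, cognitive = social = 2, velocity clamp 20% of
range) over the full box H ∈ (0.01, 1.2), W ∈ (10, 300), C ∈ (2, 999).
Particles are initialized stratified by role — positions drawn from
forward / reflected / diastolic bands and sorted — which avoids the
dominant failure basin in which one wide Gaussian swallows the systolic
complex. Two independently initialized stage-1 runs are kept by default
and the better one seeds stage 2, which restarts the swarm inside a box
shrunk to ±10% of each parameter's range around the stage-1 optimum
(50 iterations, inertia 0.6 → 0.3). The ordering constraint is enforced
by a penalty (a fixed charge per violated inequality plus a term
proportional to the violation) with feasibility repair (sorting the C
components) at initialization. An optional bounded Levenberg–Marquardt
polish runs from the swarm optimum and is kept only when it improves
the objective and preserves ordering and bounds.

All randomness flows through the configuration seed; per-episode seeds
in batch fitting are derived from (seed, episode index), so batch
results are independent of scheduling order (and deliberately *not*
invariant under episode reordering).

Under the default study conditions (physiologic random truths, noise
SD 0.01) the fitter recovers the reflected peak position with median
error ≈ 2–3 samples and its height within ≈ 0.02; noiseless pulses are
recovered to machine precision after polish. Roughly 1 fit in 25 lands
in a poorer basin — the median-based accuracy contracts absorb this.

## Synthetic data: what it emulates, what it does not

The train generator concatenates per-beat model curves (each resampled
to its beat duration), adds sinusoidal baseline wander (< 0.05 Hz) and
white noise, and marks R-peaks 150 ms before each foot with a narrow
spike template. Defaults are the study conditions: 1000 Hz sampling,
mean RR 0.8 s with 10 ms jitter, beat shape H = (0.75, 0.70, 0.30),
W = (55, 90, 180), C = (140, 250, 600), noise SD 0.01, wander amplitude
0.1 at 0.02 Hz. The third Gaussian is placed late so the diastolic
decay runs into the next foot, as in real radial recordings — this is
also what makes feet localizable. Records begin and end mid-cycle (the
lead-in is the tail of a virtual previous beat) so the signal is
beat-stationary over its whole span. Ectopic beats are emulated as a
40% RR shortening; premature-beat morphology change is not modeled.
The ECG channel is a timing template, not physiologic ECG morphology.

The cohort generator draws each subject-level index independently per
sex × SBP-category cell from normal distributions with the bundled
reference means/SDs (cell sizes 22/29/33/21 men and 17/25/25/18 women,
190 subjects). Drawing indices independently means within-subject
consistency (e.g. `C_ref_forw = C2 - C1` row-wise) is *not* enforced —
each column matches its own marginal distribution, which is exactly
what the ANOVA consumes. SBP is drawn truncated to its category range
so labels and values never disagree. Passing tests on these cohorts
demonstrates the inference machinery under the stated group structure;
they say nothing about measurement error in real recordings, inter-site
variation, or non-normal index distributions.

## Statistics

SBP categories are `<=110`, `111-120`, `121-130`, `>=131` mmHg with
readings rounded half-up to integers first (auscultatory pressures are
integer-valued in practice; configurable). The two-way ANOVA fits
`response ~ sex * sbp_category` with sum-to-zero coding and reports
Type III sums of squares by default — the convention of the major
commercial statistics packages for unbalanced designs — with Type II
available by flag. For balanced designs both coincide with the textbook
closed form (verified in tests). Degenerate inputs have defined
behavior: a zero-variance response reports F = 0, p = 1 for every
effect; empty cells or zero residual degrees of freedom raise explicit
design errors; single-subject summary cells report SD 0 with a flag.
Significance is fixed a priori at 0.05 and reported in NS / P<0.05 /
P<0.01 buckets. No multiple-testing correction is applied across the
six indices, matching the analysis this package reproduces.

## Numerical choices and problem sizes

Tests and the acceptance script use: 200 seeded cohorts for the
headline ANOVA checks, 2000 for type-I error control, 50 random truths
for parameter recovery, and 16–20-subject waveform cohorts (10 episodes
each, reduced swarm settings) for end-to-end determinism — sizes chosen
so the full suite completes in minutes while keeping the Monte-Carlo
error of every asserted proportion well below its margin.

## Known limitations

* Foot localization accuracy is model-limited (above); millisecond
  claims at high noise are not attainable for Gaussian-model beats.
* The decomposition is only locally identifiable: strongly overlapping
  sub-waves admit near-equivalent parameterizations, and occasional
  basin failures are absorbed by median-based contracts rather than
  eliminated.
* The exact half-width convention (σ-scale vs FWHM) is a pure
  reparameterization; this package treats W as the Gaussian σ-scale.
  Peak positions and heights — the quantities the indices use — are
  unaffected.
* The cohort generator reproduces marginal cell distributions, not the
  joint distribution of indices within subjects.
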