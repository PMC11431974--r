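---
title: "P wave analysis for ablation-outcome studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{P wave analysis for ablation-outcome studies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwavetools)
```

## The problem

The P wave of the 12-lead ECG is the electrical signature of atrial
depolarisation. In patients undergoing pulmonary vein isolation (PVI) for
paroxysmal atrial fibrillation, pre-procedural P wave abnormalities —
prolonged duration, reduced voltage, reduced area, inter-atrial block —
reflect atrial remodelling and have been associated with ablation failure.
`pwavetools` implements the full measurement chain needed to study such
associations: signal preprocessing, automatic P wave delineation with
manual override support, extraction of the six standard P wave parameters,
and the cohort-level statistics (group comparisons and univariable hazard
ratios) that relate them to outcome.

Because clinical recordings of this kind are not publicly deposited, the
package includes a first-class synthetic 12-lead ECG generator with exact
ground-truth fiducials; every stage of the pipeline is validated against
it.

## Parameters and their definitions

For each lead, measurements from the first 20 clean beats are averaged
into one number per parameter (beat-level measurements are averaged, not
beat waveforms):

* **PWD** (ms): time from P onset to P offset.
* **PWDc** (ms): PWD corrected for heart rate with the additive Hodges
  adjustment, `PWDc = PWD + 1.75 (HR - 60)`. At 60 bpm the correction is
  the identity. The heart rate is the recording-level median-RR rate,
  applied to the lead-mean PWD.
* **PWV** (mV): the maximal vertical distance of the P wave from the
  isoelectric line, signed by the dominant phase.
* **PWA** (ms·mV): the P wave area. Two estimators are reported: the
  trapezoidal integral of the absolute deviation from the isoelectric line
  (primary), and the triangle approximation `0.5 · PWD · |PWV|`
  (secondary). On a triangular wave the two agree to discretisation.
* **PWDisp** (ms): maximum minus minimum P wave duration, computed both
  across the twelve lead means (global) and across the 20 beats within
  each lead (per-lead); both are reported because either convention
  appears in the applied literature.
* **PTFV1** (mm·s): for a biphasic V1 P wave, the product of the terminal
  phase's absolute peak amplitude (at 10 mm/mV) and its duration, stored
  signed (negative for the common negative terminal phase); 0 for
  monophasic V1. Values beyond 0.03 mm·s in magnitude are conventionally
  called abnormal.
* **IAB** (flag): inter-atrial block, defined as maximal per-lead PWD
  ≥ 120 ms (uncorrected, configurable) together with biphasic P
  morphology in at least one of leads II, III, aVF (an `all`-leads rule is
  available for the stricter advanced-IAB convention).

## Preprocessing

The analysis chain applies a second-order Bessel bandpass (1–50 Hz) and a
biquad mains notch (50 Hz, Q = 30 by default; configurable to 60 Hz).
R's `signal` package provides the s-plane and bilinear transforms; the
order-2 Bessel analog prototype is constructed from the roots of the
reverse Bessel polynomial, normalised numerically to a −3 dB frequency of
1 rad/s. The designed filter is verified in the tests against its own
analytic transfer function (−3 dB at exactly 1 and 50 Hz).

Filtering defaults to zero-phase (forward–backward) application, which
squares the magnitude response but adds no group delay: fiducial timing
must not be biased by the filter. The first and last 0.5 s of a recording
are excluded from beat selection to avoid settling transients. The
bandpass is applied once per analysis.

Two properties of this filter matter downstream and are worth stating
plainly, because they were measured during development:

1. The 1 Hz high-pass leaves a low-frequency "droop" under each beat
   proportional to the net area of the QRS and T waves. Its linear
   component cannot bias a chord-based boundary detector (the chord and
   the curve tilt together), but its curvature can, by several
   milliseconds.
2. The 50 Hz low-pass smears sharp corners over roughly ±7 ms, so the
   filtered waveform's onset corner genuinely sits 2–3 ms before the
   unfiltered one. This is a property of the filter, not of the
   delineator; delineation accuracy is therefore validated against the
   ground truth of the signal the delineator actually sees.

## Delineation

Per lead and beat the chain is:

1. **R peaks**: threshold detector on the absolute amplitude (60% of the
   99.5th percentile) with a 250 ms refractory rule, run once on lead II.
2. **Heart rate**: `60000 / median RR (ms)` — robust to a missed beat.
3. **T end**: tangent method — the tangent at the steepest point of the T
   descent, intersected with the local baseline (a fixed-window method is
   available).
4. **P peak**: the extremum of deviation from the isoelectric line among
   candidates whose width at half prominence is at least 15 ms; short
   noise spikes lose to the P wave even when taller.
5. **P onset**: the chord rule. Over the window from the T end to the P
   peak, draw the chord between the window endpoints on the standard
   clinical paper grid (25 mm/s, 10 mm/mV) and take the sample with the
   extreme signed perpendicular distance — the point of maximal excursion
   on the baseline side, which is where the wave leaves the isoelectric
   line. Ties break to the earliest sample. (The literal unsigned-distance
   variant is degenerate — points on the chord minimise it — and is kept
   only for comparison behind `extremum_rule = "unsigned_max"`.)
6. **P offset**: the mirrored chord rule from the P peak to the QRS onset
   anchor (taken 60 ms before the R peak), ties to the latest sample. A
   `threshold_return` variant is available.

Three refinements, all applied at the pipeline level (the exported
`detect_*` operations implement the pure rules):

* **Apex-adjacent chords.** For a biphasic P the chord anchored at the
  single global extremum sweeps across the opposite phase and the
  mirrored rule degenerates (measured 25–40 ms V1 offset errors). The
  onset chord therefore targets the *first* qualifying apex and the
  offset chord starts from the *last*; for monophasic waves both equal
  the P peak. Qualifying apices must reach 25% of the dominant deviation
  and lie within 150 ms of it (P phases are contiguous; residual filter
  droop humps elsewhere in the TP segment are excluded by both rules).
* **Local detrending and departure refinement.** One refinement iteration
  re-estimates the isoelectric line by fitting a local cubic to the
  search window with the provisional P support masked, subtracting it,
  and re-running detection. The chord extremum then *localises* each
  boundary, and the final index applies the complementary definition of
  the P boundary — the first sustained rise above the isoelectric line —
  with a noise-adaptive threshold (3 robust SDs of the detrended
  baseline, floored at two ADC quanta) and first-order compensation of
  the threshold-crossing delay. On noise-free input every step is exactly
  null.
* **Cross-beat consensus.** The ~20 beats of a lead provide a robust
  prior: beats whose apex-to-boundary interval deviates from the lead
  median by more than 25 ms re-run the chord extremum restricted to the
  median interval ± 25 ms. This suppresses occasional argmin outliers in
  the shallow part of the distance profile under noise without coupling
  ordinary beats.

Manual corrections are file-based: an annotation CSV with
`provenance = "override"` records replaces detected fiducials with the
same (lead, beat, kind) key before any measurement.

### Measured accuracy

With the default synthetic morphology (below), at 1 kHz:

* noise-free recordings, delineated directly: onset and offset exact
  (0 ms mean absolute error);
* noise-free recordings through the full 1–50 Hz chain: ≈ 2–3 ms — the
  filter's own corner displacement;
* white noise of SD 0.02 mV through the full chain: ≈ 5–6 ms mean
  absolute error for both boundaries.

For Gaussian-shaped P waves the chord rule carries an additional
smooth-tail bias: the tangency point where the curve's slope equals the
chord's sits inside the support wherever the chord is steeper than the
tail (≈ 2 ms for the long onset chord, ≈ 11–14 ms for the short mirrored
offset chord). This is a known property of chord/trapezium boundary
detectors, quantified here by the package's own examples.

## The synthetic generator

Each beat is placed on an analytic template: a triphasic Q–R–S complex
(fixed 20/50/30% phase proportions at −12%/100%/−25% of the R amplitude,
so its low-frequency content resembles a real complex rather than a
monophasic spike), a half-sine T wave, and a P wave whose support ends a
configurable PR segment before QRS onset. True fiducials are the analytic
support endpoints, so the ground truth involves no delineation
circularity. Defaults emulate the target acquisition: one minute, twelve
leads, 1 kHz, 16 bits over ±5 mV (samples are quantised to that grid),
sinus rhythm at 70 bpm.

P wave shapes: `triangular` (default), `gaussian` (truncated at ±3σ and
renormalised so the declared duration is the literal support), and
`biphasic` (two opposite-signed half-sine phases; V1's default). The
default is triangular because a boundary-truth validation waveform must
have an operationally identifiable boundary: the truncated Gaussian's
tail stays below one ADC quantum for several milliseconds, so its
"analytic onset" is not a measurable landmark, whereas the triangular
corner is. Gaussian humps are retained precisely to study that smooth-tail
behaviour. Default per-lead amplitudes (0.09–0.26 mV, negative in aVR,
biphasic in V1) and the 115 ms default duration were chosen once to
bracket the values such cohorts report; no amplitude or duration
distributions were available to copy.

What the generator deliberately does **not** emulate: pathological
rhythms (AF episodes, ectopy), respiratory modulation, electrode motion
artefacts, or inter-patient morphology correlation. Passing recovery
tests on this generator therefore demonstrates the correctness of the
measurement chain under controlled conditions, not clinical performance
on arrhythmic recordings.

The cohort simulator draws a binary risk covariate with a specified true
hazard ratio under an exponential event-time model censored at 12 months,
sampling conditionally on outcome (Bernoulli posterior for the covariate,
truncated exponential for event times) so the requested arm sizes are
exact while a Cox fit recovers the true hazard ratio in expectation.
Because arm sizes are fixed, Wald intervals are slightly conservative on
these cohorts; the unconditional two-group design is used when checking
interval calibration.

## Statistics

* Group summaries are mean ± SEM (sample SD over √n).
* Continuous comparisons are gated on per-group Shapiro–Wilk normality at
  α = 0.05: both normal → two-sided Welch t-test (unequal variances — the
  arms are 154 vs 57); otherwise Mann–Whitney U with the tie-corrected
  normal approximation.
* 2×2 tables use Fisher's exact test when any expected cell is below 5,
  else Pearson's χ² without continuity correction.
* Hazard ratios come from a single-covariate Cox proportional-hazards fit
  written in this package: Newton–Raphson on the partial likelihood with
  Breslow tie handling and Wald 95% intervals, cross-checked in the tests
  against an independent survival implementation to 10⁻⁴ in the
  coefficient. Monotone likelihoods (complete separation) are flagged and
  returned without an interval. Continuous covariates are z-standardised
  by default so hazard ratios are per SD — per-millisecond hazard ratios
  for duration-scale variables would be uninformatively close to 1; the
  scale is recorded in the report's `hr_scale` column.
* Significance is two-sided at α = 0.05 with no multiplicity adjustment
  across leads, matching practice in this literature; a Benjamini–
  Hochberg column is emitted alongside for transparency.
* Intraobserver variability of paired re-measurements is summarised as
  the mean ± SEM of absolute differences and as a percentage of the mean
  paired level (the denominator convention is this package's choice; the
  protocol size helper documents the 22 × 12 × 20 = 5280 paired P waves
  of a two-day re-reading study).

## Numerical and design choices worth knowing

* Sample indices are 0-based in files and APIs; times are `index / fs`.
* Amplitudes are millivolts everywhere in memory; readers convert µV and
  ADC counts at ingest.
* The chord geometry is computed on the 25 mm/s, 10 mm/mV clinical grid.
  The extremum location is invariant under uniform rescaling; the grid
  fixes the meaning of "perpendicular".
* IAB uses uncorrected PWD by default (the definition is a threshold on
  PWD, not PWDc); switchable.
* Morphology phases must last ≥ 20 ms with an extremum ≥ 0.025 mV —
  noise-robustness thresholds of this package, not published values.
* Beat selection takes the first 20 clean beats; with fewer available the
  pipeline proceeds with what it has and records a warning.
* Test-suite problem sizes (10–50 recordings of 20–60 s; 200 Cox
  replicates; 2000 calibration replicates) were chosen to make the suites
  informative at interactive runtimes; the acceptance script uses 50
  recordings per arm.

## Known limitations

* The offset chord's smooth-tail bias (above) means Gaussian-like P waves
  measure slightly short; real P waves lie between the triangular and
  Gaussian idealisations.
* The Hodges adjustment is additive and was developed for QT intervals;
  its transfer to P wave durations is a convention of this analysis
  lineage, not a validated correction.
* No multivariable modelling: hazard ratios are univariable by design and
  confounding is not addressed.
* WFDB records are not read; recordings interchange via the documented
  plain-text matrix format.
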