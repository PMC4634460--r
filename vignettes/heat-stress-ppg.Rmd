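---
title: "Time-domain PPG/APG analysis of heat stress: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain PPG/APG analysis of heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgheat)
```

## The analysis chain

`ppgheat` implements a complete time-domain pipeline for deciding, from a
short fingertip photoplethysmogram (PPG), whether a subject was measured at
rest or after exertional heat stress. The chain is: zero-phase Butterworth
bandpass (0.5–7 Hz) → cascaded three-point central differences, giving the
acceleration plethysmogram (APG) → a/b-wave fiducials → fourteen
energy/amplitude/slope features plus RMSSD → a Mann–Whitney separability
screen with Holm–Bonferroni correction → leave-one-out classification with
Mahalanobis, LDA, QDA and linear-SVM classifiers, summarized per feature by
the overall accuracy (OA), the mean F1 over all classifier × comparison
cells.

The underlying physiological assumptions are modest: heat stress raises
heart rate and reduces pulse volume and beat-to-beat variability; both
effects leave signatures in the amplitude and curvature of the pulse
waveform that survive a 20-s recording. The features are deliberately
simple — sums of squared samples over fiducial-delimited spans, amplitudes
at fiducials, and one interval statistic — so each has a direct oracle
(exhaustive summation or hand arithmetic) against which the implementation
is tested.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band edges `low`, `high` | 0.5, 7 | Hz | retains the pulse fundamental (≈1.3–2.4 Hz) and the harmonics shaping a/b waves, removes baseline wander and noise |
| filter `order` | 2 | – | second-order design per pass; forward–backward application squares the magnitude |
| `fs` | 367 | Hz | the sampling rate of the instrument the analysis targets |
| `duration` | 20 | s | short enough for field use, long enough for ≈15–45 beats |
| screen `alpha` | 0.05 | – | conventional family-wise level, applied over all 42 tests jointly |
| `test` | `"unpaired"` | – | Mann–Whitney U; `"paired"` switches to the Wilcoxon signed-rank for sensitivity analysis (the within-subject design admits either reading) |
| SVM cost | 1 | – | plain soft margin; none of the classifiers is tuned |

Two deliberately fixed conventions: sample indices in fiducial files are
0-based (documented in the file headers), and colon ranges `S(x:y)` include
both endpoints, which gives the exact identity
`f1 + f3 = f2 + Σ S(B[n])²` over shared spans — used as a test invariant.

## The synthetic cohort generator

The study data this pipeline targets (40 emergency responders, one resting
and three post-exercise recordings each) are not openly deposited, so the
package ships a generator whose defaults encode the published cohort
conditions:

* heart rate 76.0 ± 14.7 bpm at rest; 133.1 ± 29.9, 143.9 ± 23.6 and
  138.2 ± 25.7 bpm after the three exercise bouts;
* a PPG aa-area energy that falls to 580/790 ≈ 73% (E1) and
  560/790 ≈ 71% (E2, E3) of baseline, with a baseline between-subject
  coefficient of variation of ≈ 1.3/7.9 ≈ 0.165 — both taken from the
  published stage summaries;
* APG a/b amplitudes and energies that *rise* after stress, because the
  faster beats are absolutely narrower and steeper while widths are fixed
  fractions of the period;
* RMSSD that falls after stress (beat-to-beat jitter 3 bpm at rest vs
  2 bpm after exercise), the classical parasympathetic-withdrawal
  signature.

Each beat is a sum of two smooth bumps: a dominant systolic wave and a
smaller, later diastolic (reflection) wave. Three modelling choices deserve
explanation because simpler variants provably fail:

1. **Wrapped evaluation.** Bumps are evaluated with circular distance in
   beat fractions, so every beat starts and ends at exactly the same level
   and equal-period beats concatenate smoothly. Plain Gaussian bumps with a
   non-negligible diastolic tail leave a step at each beat join whose
   second derivative dwarfs the physiological curvature and hijacks a-wave
   detection.
2. **Systolic skew.** The systolic bump is a two-piece Gaussian with a
   narrower rising side (skew −0.2 by default, subject SD 0.15, clamped to
   fast-rise values). For a *symmetric* bump the APG b/a amplitude ratio is
   a mathematical constant (−1/(2e^{−3/2})) independent of amplitude, width
   and heart rate — every synthetic subject would have the same ratio, and
   the small residual stage drift introduced by the bandpass filter would
   then look like a strong group difference. Real cohorts show the
   opposite: a wide between-subject spread of the b/a ratio and essentially
   no stress separation. Subject-level skew (plus smaller width, diastolic
   amplitude and timing factors) reproduces that spread; the skew does not
   perturb the energy features appreciably because the two-piece Gaussian's
   integral is skew-invariant.
3. **Calibrated amplitude multipliers.** The post-exercise amplitude
   factors are computed at construction time so that the *filtered*
   aa-energy ratio to baseline equals the published ratios exactly for the
   nominal morphology; a closed-form `sqrt(energy ratio)` is insufficient
   because the bandpass attenuates the narrower post-exercise beats
   slightly differently.

Ground-truth fiducials are produced by running the noise-free signal
through the same preprocessing used for analysis and locating, per beat,
the APG maximum in the early beat window and the first *negative* local
minimum after it; the first and last located beats are discarded because
filter startup makes them untrustworthy annotations. Additive white
Gaussian noise (SD 0.05 of the unit systolic amplitude) is applied after
the truth is recorded.

**What the generator does not emulate:** motion artifacts, sensor
saturation, respiratory modulation, the c/d/e waves of the APG (which merge
after heat stress in real data), or the empirical sign of the *PPG*
amplitude at the b wave. On that last point: in the published data the
filtered PPG is negative at both a and b indices, implying b falls very
early on the systolic upstroke; with any smooth two-bump pulse the APG
minimum necessarily sits at the systolic crest, where the DC-removed PPG is
positive, so the synthetic PPG b/a ratio is negative where the published
one is ≈ +0.7. Every APG sign (a wave positive, b wave negative, ratio
negative) is reproduced. Consequently, passing tests demonstrate that the
pipeline recovers the engineered effect structure — not that the synthetic
waveforms are indistinguishable from clinical recordings.

## Numerical choices

* **Zero-phase filtering** is realized by forward–backward application with
  odd-reflection padding of 3/`low` seconds at each end and zero initial
  conditions. The padding must outlast the high-pass transient (≈2 s at
  0.5 Hz); the central region agrees with an independent reference
  implementation to < 10⁻⁶.
* **Derivative edges** use one-sided first differences; `valid_range` marks
  the two samples at each end as untrusted. The causal form of the cascade,
  provided for streaming use, reproduces the centred result delayed by
  exactly two samples.
* **Rank tests** use the exact permutation distribution for small tie-free
  samples (combined n ≤ 20 for Mann–Whitney, ≤ 15 nonzero differences for
  the signed rank) and the tie-corrected, continuity-corrected normal
  approximation otherwise.
* **Equal priors / balanced class weights.** The design is balanced (40 vs
  40), but leave-one-out training folds never are: the held-out record's
  class always has one fewer member. Classifiers that estimate priors from
  the fold therefore vote systematically *against* the held-out class,
  which drives error rates on effect-free data far below chance. The
  discriminants use equal priors and the SVM uses balancing class weights;
  Mahalanobis ignores priors by construction.
* **F1 in count form.** F1 is computed as `2TP/(2TP+FP+FN)`, identical to
  the harmonic mean of SE and PP whenever both are defined, but still
  defined (zero) when a classifier predicts no positives. SE and PP are
  reported as `NA` on zero denominators rather than 0.
* **Ties and degenerate cases.** Exact distance/posterior ties resolve to
  the baseline class (conservative for sensitivity). A rank-deficient
  feature matrix (e.g. a duplicated column) is reduced to its linearly
  independent span before the covariance-based classifiers. A single-point
  class in a fold falls back from per-class to pooled covariance (QDA falls
  back to the shared-covariance discriminant). Beats violating the
  `A[n] < B[n] < A[n+1]` interleaving are dropped and counted, not
  repaired.
* **RMSSD** follows the standard successive-difference definition; the
  literal "root mean square of the intervals" reading occasionally implied
  by loose phrasing is available as `method = "literal"` but is not used
  anywhere in the pipeline.
* **OA aggregation** is the arithmetic mean of all 12 F1 cells (3
  comparisons × 4 classifiers), which reproduces published OA columns from
  their printed cells arithmetically; the alternative per-comparison-first
  averaging does not.

## Null calibration and the paired design

The generator's `paired = TRUE` default draws subject-level random effects
(amplitude, heart-rate offset, morphology) once per subject, shared across
stages, matching the within-subject protocol. This has a consequence worth
knowing about: under a zero-effect configuration, a held-out record's
same-subject siblings — carrying the *opposite* label and nearly identical
feature values — remain in the training fold, so leave-one-out estimates
on paired null data are strongly anti-predictive. That is a property of
applying record-level LOOCV to paired designs, not an implementation
artifact. Calibration checks (error rates inside the binomial band around
50%, uniform screen p-values) therefore use `paired = FALSE`, which makes
records exchangeable and independent; effect-recovery checks use the
paired design as in the study.

Problem sizes used by the test suite, chosen to balance statistical
resolution against runtime: the effect-recovery study runs 50 replicate
40-subject paired cohorts; null calibration uses one 40-subject unpaired
cohort for the error-rate band plus 120 replicate 12-subject unpaired
cohorts for p-value uniformity (tested on per-feature, per-comparison
series, which are i.i.d. across replicates — pooling all 42 p-values of one
screen would mix strongly correlated tests) and for the family-wise
false-positive rate of the Holm-corrected screen.

## Known limitations

* Energies are sums, not rates: they scale with recording length and beat
  count, so records of different durations are not directly comparable.
* Feature aggregation over beats (mean for f4–f7) discards beat-to-beat
  morphology variability.
* The fiducial locator assumes annotations or synthetic ground truth for
  beat onsets; it is not a general-purpose a/b detector for noisy field
  recordings.
* The combined-feature (aa energy + RMSSD) classifier inherits RMSSD's
  sensitivity to the engineered jitter contrast, which in synthetic cohorts
  is cleaner than in ambulatory data; its near-ceiling synthetic
  performance should not be read as a clinical claim.
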