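# ppgheat

Time-domain analysis of fingertip photoplethysmogram (PPG) signals for
assessing exercise-induced heat stress.

Emergency responders working in protective equipment under tropical
conditions accumulate heat faster than they can dissipate it. The two
classical heat-strain indices are impractical in the field: body core
temperature requires an ingested telemetric pill, and heart-rate-variability
indices need long ECG recordings. This package implements an alternative
built entirely from 20-second fingertip PPG recordings: time-domain features
of the filtered pulse wave and of its second derivative (the acceleration
plethysmogram, APG) are screened for separability between rest and
post-exercise states and ranked by leave-one-out classification accuracy.
It is aimed at biosignal researchers who want a tested, reproducible
reference implementation of this analysis chain, together with a synthetic
cohort generator that makes every stage verifiable without access to
restricted clinical data.

## The method

For a record `S` sampled at `fs = 367` Hz:

1. **Filter** — zero-phase (forward–backward) Butterworth bandpass,
   0.5–7 Hz, order 2 per pass.
2. **Differentiate** — the three-point central difference
   `S'[n] = (S[n+1] − S[n−1]) / 2T`, applied twice, yields the APG
   `Z[n]`. The causal realization of this cascade has a two-sample latency;
   the offline form is delay-free.
3. **Fiducials** — per beat, the APG a wave (early positive peak) and
   b wave (following negative trough), as index arrays `A` and `B` with
   `A[n] < B[n] < A[n+1]`.
4. **Features** — on both the filtered PPG and the APG, using the same
   index arrays (inclusive ranges):
   - energies `f1 = Σₙ Σ S(A[n]:B[n])²`, `f2 = Σₙ Σ S(A[n]:A[n+1])²`,
     `f3 = Σₙ Σ S(B[n]:A[n+1])²`
   - amplitudes `f4 = S(B[n])`, `f5 = S(A[n])`, ratio `f6 = S(B[n])/S(A[n])`,
     slope `f7 = (S(B[n]) − S(A[n]))/(B[n] − A[n])`, averaged over beats
   - RMSSD — the root mean square of successive differences of the
     beat-to-beat (aa) intervals `aa[n] = A[n+1] − A[n]`, in seconds.
5. **Screen** — two-sided Mann–Whitney tests of baseline (BE) against each
   post-exercise stage (E1, E2, E3) for all 14 features (42 tests), with
   Holm–Bonferroni correction over the whole family and the mean raw
   p-value per feature.
6. **Classify** — leave-one-out cross-validation per feature and
   comparison with four classifiers (Mahalanobis distance with per-class
   covariance, LDA, QDA, linear SVM), reporting sensitivity
   `SE = TP/(TP+FN)`, positive predictivity `PP = TP/(TP+FP)`, their
   harmonic mean F1, and each feature's overall accuracy
   (OA = mean F1 across the 12 classifier × comparison cells). A combined
   two-feature classifier (aa energy + RMSSD) is run with LDA.

## Worked example

```r
library(ppgheat)

cohort <- generate_cohort(cohort_config(n_subjects = 40, seed = 1))
res <- run_heat_stress_analysis(cohort)
res
#> <heat_analysis>
#>   records: 160 (40 subjects x 4 stages)
#>   filter: Butterworth order 2, 0.5-7 Hz, zero-phase
#>   screen: 42 tests (unpaired), 35 Holm-significant at alpha = 0.05
#>   best feature: amp_b_ppg (OA = 89.55%)

head(res$ranking, 5)
#>         feature    oa
#> 1     amp_b_ppg 89.55
#> 2 energy_ba_apg 84.75
#> 3 energy_aa_apg 84.70
#> 4 energy_ab_apg 84.44
#> 5 energy_aa_ppg 84.06

res$screen[res$screen$feature == "energy_aa_ppg",
           c("feature", "mean_be", "mean_e1", "p_e1", "p_mean")]
#>         feature  mean_be  mean_e1         p_e1       p_mean
#> 1 energy_aa_ppg 658.6146 512.5536 2.226087e-09 8.998861e-10

res$combined[, c("comparison", "se", "pp", "f1")]
#>   comparison   se   pp   f1
#> 1   BE_vs_E1 97.5 97.5 97.5
#> 2   BE_vs_E2 97.5 97.5 97.5
#> 3   BE_vs_E3 97.5 97.5 97.5
```

Reading the numbers: the PPG aa-area energy drops from 659 to 513 arbitrary
units² after the first exercise bout (the pulse loses energy under heat
stress) and separates the stages at p ≈ 10⁻⁹, surviving the 42-test Holm
correction; its leave-one-out overall accuracy is 84%. The APG b/a ratio
(`ratio_ba_apg`), by design of the synthetic cohort, carries almost no
stress information and ranks near the bottom. Combining the aa energy with
RMSSD pushes sensitivity and positive predictivity to 97.5% on this
synthetic cohort. `autoplot()` on `res$screen` or `res$classification`, and
`plot_ppg_record()` on a single record, visualize these tables.

Records, annotations and cohorts round-trip through plain CSV
(`write_cohort()` / `read_cohort()`), and a thin command-line front end is
included at `inst/cli/ppgheat-cli.R` with `simulate` and `run` subcommands.

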