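# mrsidh

Non-invasive prediction of IDH (isocitrate dehydrogenase) mutation
status in gliomas from single-voxel ¹H-MR spectroscopy. IDH-mutant
tumors accumulate 2-hydroxyglutarate (2-HG, resonating near 2.24 ppm)
and show further spectral changes (elevated myo-inositol around
3.5–4.1 ppm; IDH-wild-type tumors instead show stronger lactate/lipid
signal near 1.3 ppm). **mrsidh** turns these differences into a tested,
reusable classification pipeline for spectra acquired on *different*
scanners — different field strengths, spectral widths and point counts:

1. **Quality gate** — amplitude thresholds on Cho (> 0.2), Cr (> 0.1),
   M-Ins (> 0) and Cr2 (> 0) in vendor arbitrary units, plus an
   exclusion ledger that always balances.
2. **Harmonization** — each spectrum is rigidly shifted so its choline
   peak (3.22 ppm) lands on the anchor, linearly resampled onto the
   4.2–0.5 ppm window of the 3 T reference grid, and normalized to unit
   total area.
3. **Classification** — features ranked by absolute Welch *t*; the
   feature count picked by stratified cross-validation with in-fold
   re-ranking; a linear SVM (cost fixed at 1) on standardized selected
   features; decision threshold fixed at 0, with
   `mut` the positive class:

   minimize ½‖w‖² + C Σᵢ max(0, 1 − yᵢ(w·xᵢ + b)),  C = 1.

4. **Diagnostics** — sensitivity, specificity, accuracy, prevalence
   (exact Clopper–Pearson 95% CIs), PPV/NPV (logit CIs, flagged),
   LR⁺ = sens/(1−spec) and LR⁻ = (1−sens)/spec (log-method CIs), and
   ROC/AUC by the Mann–Whitney formulation.

A synthetic-spectrum generator (Lorentzian basis with the
mutation-specific group structure, noise, baseline, frequency jitter and
arbitrary-unit scaling) substitutes for patient cohorts, so the entire
workflow is reproducible and testable offline.

Everything is tidyverse-shaped: cohorts are tibbles with the intensity
vectors in a list-column, every verb takes a data frame first and
returns a tibble, fitted models have `tidy()`/`glance()` methods, and
each result type has an `autoplot()`.

## Worked example

Train on a simulated 3 T cohort (17 mutant / 17 wild-type), predict a
simulated 1.5 T cohort (23 / 44) — the full cross-scanner workflow:

```r
library(mrsidh)

res <- run_end_to_end(pipeline_config(seed = 1))
res
#> <mrs_pipeline_result> seed 1 | train 34 spectra, validation 67 spectra | k = 1 | AUC = 1.000
#> confusion (mut positive): tp=23 fn=0 fp=1 tn=43
#> sensitivity  100.00% ( 85.18-100.00)
#> specificity   97.73% ( 87.98- 99.94)
#> accuracy      98.51% ( 91.96- 99.96)
#> lr_positive   44.00  (  6.34-305.44)
#> lr_negative    0.00  (    NA-    NA)
#> ppv           95.83% ( 75.65- 99.42)
#> npv          100.00% ( 91.78-100.00)
#> prevalence    34.33% ( 23.15- 46.94)
```

The cross-validated selection kept a single feature, and `tidy()` shows
which: a grid point at 2.25 ppm — the 2-HG resonance — with a positive
weight (higher intensity pushes toward `mut`):

```r
tidy(res$model)
#> # A tibble: 1 × 6
#>   feature   ppm statistic weight center scale
#>     <int> <dbl>     <dbl>  <dbl>  <dbl> <dbl>
#> 1     213  2.25      12.0   1.99  0.374 0.203
```

Every number above is on synthetic data with assumed effect sizes; it
demonstrates that the machinery recovers and transfers a planted
contrast across a field-strength change, not clinical performance.

Individual stages compose with the pipe:

```r
cohort <- simulate_cohort(sim_config(), n_mut = 10, n_wt = 20, seed = 7)
harmonized <- cohort |>
  apply_exclusions() |>
  harmonize_cohort()
model <- mrs_train(harmonized)
predict(model, harmonized)          # tibble: id, score, label
autoplot(harmonized, group_mean = TRUE)
```

There is also a thin CLI over the same functions
(`inst/cli/mrsidh.R`) with subcommands `simulate`, `qc`, `harmonize`,
`train`, `predict`, `evaluate` and `demo`.

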