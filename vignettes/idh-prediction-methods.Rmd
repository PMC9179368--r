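---
title: "Predicting IDH mutation status from single-voxel 1H-MR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting IDH mutation status from single-voxel 1H-MR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mrsidh)
```

## The problem

Gliomas carrying a mutation in isocitrate dehydrogenase (IDH) accumulate
the oncometabolite 2-hydroxyglutarate (2-HG), which resonates near
2.24 ppm in a proton MR spectrum. IDH status defines the diagnostic
category and prognosis of a diffuse glioma, but its tissue-based
determination requires surgery. mrsidh implements a purely computational
route: classify a routine single-voxel ¹H-MR spectrum of the tumor as
IDH-mutant or IDH-wild-type, even when training and test spectra come
from different scanners — different static fields (3.0 T vs 1.5 T),
spectral widths, and therefore entirely different frequency grids.

The pipeline has five stages, each usable on its own:

1. **Quality gating** (`qc_cohort()`, `apply_exclusions()`) — amplitude
   thresholds on four reference metabolites, plus bookkeeping of
   predefined exclusions.
2. **Harmonization** (`harmonize_cohort()`) — a rigid ppm shift
   anchored at the choline peak, linear resampling onto a fixed
   reference grid, and total-area normalization.
3. **Feature selection** (`rank_features()`,
   `select_feature_count()`) — absolute Welch *t* ranking with the
   feature count chosen by stratified cross-validation.
4. **Classification** (`mrs_train()`, `predict()`) — a linear
   soft-margin SVM with the cost fixed at 1 on standardized selected
   features.
5. **Evaluation** (`confusion()`, `diagnostic_report()`,
   `roc_auc()`) — the full diagnostic-accuracy panel with confidence
   intervals.

A synthetic-spectrum generator (`simulate_cohort()`) stands in for
patient cohorts, so every stage is testable end to end.

## The coordinate system

A spectrum is an intensity vector on a chemical-shift axis in ppm. For a
transmitter frequency $f_0$ (MHz) and spectral width $SW$ (Hz), the axis
spans $SW / f_0$ ppm with uniform spacing $SW / (f_0\,n)$, ordered high
to low (the NMR plotting convention; all window arguments in the package
are `(high, low)` pairs). When $f_0$ is not recorded it defaults to
$42.576 \times B_0$ MHz from the proton gyromagnetic ratio; for measured
data the true synthesizer frequency should be passed, since real magnets
deviate slightly from their nominal field. The window center defaults to
4.7 ppm (water); its absolute placement is irrelevant after choline
anchoring, but a convention is needed for simulation and plotting.

The two built-in regimes are `regime_params("3T-original")` (3.0 T,
1200 Hz, 1024 points, TE 30 ms; 0.0092 ppm/pt) and
`regime_params("1.5T-validation")` (1.5 T, 1000 Hz, 1024 points;
0.0153 ppm/pt). Note the lower field has the *wider* ppm span and the
coarser ppm sampling — this asymmetry is exactly what harmonization must
absorb.

## The synthetic data model

`simulate_spectrum()` draws

$$
y(x) \;=\; s \sum_j a_j\, m_j(\text{label})\, \varepsilon_j\,
L(x;\, c_j + \delta,\, w_j) \;+\; b(x) \;+\; \eta(x),
$$

with $L$ a unit-height Lorentzian ($L(x; c, w) = (w/2)^2 / ((x-c)^2 +
(w/2)^2)$), per-peak mean amplitudes $a_j$, class multipliers $m_j$,
log-normal amplitude factors $\varepsilon_j$ (mean 1, CV 0.25), one
global frequency jitter $\delta \sim N(0, 0.01\ \text{ppm})$ per
spectrum (a calibration error, shared by all peaks), a smooth random
polynomial baseline $b$ of order 3 confined to $[0, 0.1]$, white noise
$\eta$ with sd 0.05, and an arbitrary-unit scale $s \sim U(0.5, 2)$
emulating vendor scaling.

The default basis places NAA (2.01), Cr (3.03), Cr2 (3.93), Cho (3.22),
myo-inositol (3.53), Glx (2.35), 2-HG (2.24) and a lactate/lipid
methylene signal (1.30 ppm). The class structure encodes the reported
mutant signature: 2-HG is present only in mutant spectra, myo-inositol
is elevated in mutants (multiplier 1.75), and the lactate/lipid signal
is elevated in wild-type spectra (mutant multiplier 0.4). Amplitudes are
on a unit-Cho scale (Cho 1.0, Cr 0.8, NAA 1.2, ...), chosen so the
quality-gate thresholds (Cho > 0.2, Cr > 0.1) are meaningful at the
default arbitrary-unit range. These effect sizes are simulator
parameters, not measured values: the real group contrast is known only
qualitatively, so downstream claims rest on recovery properties (can the
pipeline find and transfer whatever contrast was planted), not on
absolute performance numbers.

**Linewidths.** Peak FWHM is specified in Hz *at the 3 T reference
field* (default 10 Hz ≈ 0.078 ppm, a typical in vivo single-voxel value)
and scales proportionally with field strength, i.e. it is constant in
ppm. In vivo linewidth is dominated by susceptibility broadening and
microscopic field inhomogeneity, both proportional to $B_0$, so the
ppm-invariant model is the physically realistic regime. It is also what
makes cross-field transfer well-posed: if linewidth in Hz were
field-independent, a 1.5 T spectrum would be twice as broad in ppm as
its 3 T counterpart and no rigid-shift-plus-resampling scheme could make
the two comparable (the pointwise residual would reach tens of percent
of the peak height). Narrower defaults also run into a sampling
limit: below ~6 Hz the 1.5 T grid samples a peak with fewer than three
points per FWHM and linear resampling clips peak tops by 10–20%.

What the generator does *not* emulate: J-coupled multiplet structure and
its TE modulation (2-HG is in reality a coupled multiplet, not a
singlet), macromolecule baselines with sharp features, residual water,
phase errors, and lineshape distortions from eddy currents. Passing
tests therefore demonstrate the correctness and internal consistency of
the pipeline machinery — not clinical-grade performance on measured
spectra, which depends on exactly the distortions left out.

## Quality gating

The gate reads four amplitudes from the raw (un-normalized) spectrum —
Cho 3.22, Cr 3.03, M-Ins 3.53, Cr2 3.93 ppm — and requires Cho > 0.2,
Cr > 0.1, M-Ins > 0, Cr2 > 0 (strict inequalities, all configurable;
thresholds are in vendor arbitrary units and are cohort conventions, not
universal constants). An amplitude is the window maximum
(position ± 0.08 ppm) minus the median intensity of two flanking
0.08 ppm bands; this estimator is invariant under additive offsets,
scales linearly with the data, and needs no fitting. `apply_exclusions()`
removes predefined exclusions (`no_tumor`, `idh_undetermined`) first,
then QC failures, counting each spectrum once under the first applicable
reason, so the ledger always balances: retained + excluded = input.

```{r}
co <- simulate_cohort(sim_config(), n_mut = 5, n_wt = 5, seed = 1)
qc_cohort(co)
```

## Harmonization

All spectra are mapped onto the analysis window 4.2–0.5 ppm of the 3 T
training grid (379 points). The window excludes residual water
(~4.7 ppm) while containing every diagnostically relevant region
(4.1–3.5, 2.24, ~1.3 ppm).

- **Anchoring.** The choline peak is located in 3.22 ± 0.15 ppm as the
  intensity argmax, refined to sub-grid precision with the three-point
  parabolic vertex through the apex (clamped to half a grid step,
  skipped when the apex is not locally concave). Without the refinement
  the rigid shift is quantized to the source grid and two regimes stay
  misaligned by up to ~0.012 ppm, which at the flank of a sharp peak is
  a ~10% intensity error. The spectrum's axis is then shifted rigidly so
  the detected position lands on 3.22; a single global frequency offset
  is the dominant calibration error in single-voxel MRS, so no
  stretching is applied.
- **Snap tolerance.** Shifts below a quarter grid step are set to zero.
  They are smaller than the apex estimator's own bias, and suppressing
  them makes harmonization an exact fixed point: re-harmonizing an
  already harmonized spectrum reproduces it to machine precision
  (asserted at 1e-9 in the tests) rather than accumulating sub-step
  jitter.
- **Resampling.** Linear interpolation onto the reference grid. Linear
  (rather than spline or Fourier) resampling is monotone and
  artifact-free when moving between the 0.0153 and 0.0092 ppm spacings;
  a coverage shortfall smaller than one source grid step at the window
  edge is filled by constant extrapolation, anything larger is an
  error naming the missing range.
- **Normalization.** Division by the trapezoidal integral over the
  window, making the total area 1. This removes the vendor
  arbitrary-unit scale, the dominant cross-cohort nuisance. It assumes
  the *total* metabolite signal is comparable across classes; a
  pathology that changed every metabolite proportionally would be
  normalized away.

On noiseless paired simulations of the same signal at 1.5 T and 3 T the
harmonized vectors agree pointwise to within 5% of the choline height
and correlate above 0.99; the residual is interpolation error at peak
tops.

## Feature selection and classification

Features are the harmonized window intensities (379 per spectrum).
Discriminative power is scored by the absolute Welch two-sample
*t* statistic — Welch, because spectral intensity variances routinely
differ between groups; a constant feature is assigned statistic 0 and
ranks last, ties break toward the lower index. "Most differential" is
not a self-defining notion, so the package
fixes this convention explicitly.

The feature count $k$ is chosen from candidates (default 1, 2, 3, 5, 10,
20, 50, 100) by stratified 5-fold cross-validation in which the ranking
is **recomputed inside each training fold** — selecting features on the
full data before CV would leak the held-out labels and overstate
accuracy. Ties in mean CV accuracy go to the smallest $k$; the fold
assignment is deterministic given the config seed. The final model
re-ranks on the complete training cohort and keeps the top $k$.

The classifier is a linear soft-margin SVM, $\min \tfrac12\lVert w
\rVert^2 + C \sum_i \max(0, 1 - y_i(w \cdot x_i + b))$, with $C = 1$
(the library default, deliberately left
untuned). Selected features are standardized with training-set
statistics stored in the model — without some scaling a fixed $C$ is
meaningless across data sets. Fitting goes through e1071/libsvm with the
termination tolerance tightened to 1e-8; the tests verify the attained
primal objective against a direct numerical minimization to 1e-4. The
decision threshold is fixed at 0 (a score of exactly 0 is called
wild-type); no recalibration is done on new data, mirroring a strict
train-once / apply-unchanged protocol.

## Diagnostic reporting

With mutant as the positive class throughout: sensitivity, specificity,
accuracy and prevalence carry exact Clopper–Pearson 95% intervals
(beta-quantile form); likelihood ratios use the log method
$\exp(\ln LR \pm z\,SE)$ with $SE(\ln LR^+) = \sqrt{1/tp - 1/n_1 + 1/fp
- 1/n_2}$ and the analogous form for $LR^-$; PPV and NPV use logit
intervals and are flagged as such in the report (no single interval
method for predictive values is standard practice, so those bounds
should not be treated as reference values). Statistics with zero denominators are reported as
`NA` with a note instead of erroring, so partial reports remain
possible. The AUC is the Mann–Whitney statistic (ties counted ½),
computed from rank sums and cross-checked in the tests against explicit
pair counting.

```{r}
diagnostic_report(mrs_confusion(19, 4, 12, 32))
```

## The end-to-end experiment

`run_end_to_end()` wires the stages together on synthetic data: train on
a balanced 17/17 cohort simulated under the 3 T regime, validate on a
23/44 cohort (about one-third mutant prevalence, matching a realistic
clinical mix) under the 1.5 T regime. Problem sizes were chosen to
mirror a realistic two-center cohort scale while keeping a
ten-seed replication of the whole experiment around ten seconds. Across
ten seeds the median sensitivity and specificity of the transfer
experiment exceed 0.8 and 0.7, and the selected features fall in the
2-HG (2.24 ppm), myo-inositol (4.1–3.5 ppm) or lactate/lipid (~1.3 ppm)
regions — the pipeline rediscovers the contrast the generator planted,
across a field-strength change.

```{r, eval = FALSE}
res <- run_end_to_end(pipeline_config(seed = 1))
res$report
autoplot(res$roc)
```

## Numerical and design choices, in brief

- High-to-low ppm ordering everywhere; window arguments `(high, low)`.
- Axis convention: first point at `center + span/2`, step `span/n`.
- Gyromagnetic constant 42.576 MHz/T; `transmitter_frequency`
  overridable.
- Intensities are real absorption-mode values; complex FIDs, phasing,
  water removal and lineshape deconvolution are out of scope.
- Choline tie-breaks: toward the grid point nearest 3.22 ppm, then
  toward higher ppm (a flat spectrum anchors at the nominal position).
- Degenerate inputs error informatively: non-positive window integral,
  analysis window not covered, missing classes, single-member classes.
- CV folds are reduced (with a warning) when a class is smaller than
  the fold count; candidate feature counts above the feature dimension
  are skipped with a warning.
- Per-spectrum simulation sub-seeds are derived by counter from the
  master seed, so cohort contents do not depend on generation order.

## Known limitations

- The simulator's effect sizes are assumptions; real 2-HG detectability
  at 1.5 T and short TE is harder than the synthetic contrast suggests.
- Rigid-shift alignment cannot correct differential shifts between
  metabolites (temperature/pH effects) or lineshape differences between
  scanners.
- Total-area normalization is sensitive to gross lipid contamination,
  which inflates the denominator and deflates every other feature.
- The subgroup question of distinguishing oligodendroglioma-defining
  1p/19q codeletion within IDH-mutant tumors is deliberately not a
  supported mode: the underlying study found spectra of those subgroups
  nearly indistinguishable, and this package follows that negative
  result rather than offering an unreliable classifier.
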