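---
title: "Evolutionary model and feature selection for breast thermography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary model and feature selection for breast thermography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast tumours raise local skin temperature through angiogenesis and increased
metabolism, which makes infrared thermography a cheap, contactless screening
candidate. A single static thermogram yields, after segmentation, one
temperature matrix per breast. Classifying such exams well requires two coupled
choices: the classifier configuration (here a nu-SVM over a discrete
hyperparameter grid) and the feature subset describing the exam. `thermoga`
implements a two-stage evolutionary treatment of that coupling:

1. **Bucket of models.** A genetic algorithm (GA) over six-gene integer
   chromosomes — indices into ordered candidate lists for tolerance, gamma,
   coef0, nu, polynomial degree and kernel — searches the grid of
   `count_exhaustive(build_parameter_space())` = 540,560 distinct
   configurations (the sum over kernels of the product of each kernel's
   relevant-parameter list lengths: rbf 2,320; sigmoid 134,560; poly 403,680).
   It returns the ten best-adapted distinct configurations.
2. **Feature selection.** A second GA over binary chromosomes (one bit per
   feature column) searches for the smallest subset that classifies best,
   scored by the models from stage one.

With the default budgets (140 individuals for 30, then 100 generations) the
two stages train 4,200 and 14,000 models — 18,200 in total, about 3.37% of
what the exhaustive grid would cost before any feature selection.

## Fitness protocol

One run-level seed fixes a stratified 70/30 holdout split and a stratified
4-fold partition of the 70% part. The GA fitness of any individual (a
configuration, or a feature mask under a fixed configuration) is the mean ROC
AUC over the four inner folds; the 30% holdout is scored exactly once, by the
final returned model, to report AUC/F1/ACC/SENS/SPEC with `cancer` as the
positive class. Sharing one split across all individuals makes fitness values
comparable between and across generations, at the price of adapting to that
split — which is why final metrics come from the untouched holdout. Features
are standardised with training-fold statistics inside every fit; zero-variance
columns are left centred rather than rescaled.

Configurations that cannot be fitted at all (for instance a `nu` infeasible
for the fold's class balance) receive fitness 0 and are discarded by
selection, rather than aborting the run.

## Reproduction strategies

Each new model-selection generation is assembled from fixed quotas
(10 elites, 40 crossover children, 20 asexual variants, 10 mutants, 60 random
genomes; the feature-selection stage uses 20/40/6/74 with no asexual class).
Crossover takes a couple of two *distinct* elites and deals each child half of
the genes of each parent at random positions (integer genomes), or swaps the
head/tail segments around a uniformly drawn cutoff (binary genomes). Asexual
reproduction walks the ranked parents emitting index±1 variants per gene —
a fine-tuning move that exists because the candidate lists are ordered scales;
out-of-bounds neighbours are skipped rather than wrapped, since wrapping would
jump between regimes (e.g. from gamma 5.1 to 1e-8). Mutation changes exactly
one gene: one mutant comes from the three best, one from the three worst, the
rest from uniformly random members. Binary mutation respects a configurable
minimum number of active genes (default 1), as do crossover children, which
are repaired by activating a random bit.

Ranking is by fitness, with feature-selection ties broken in favour of fewer
active genes and then earlier discovery — the second stage's goal is the
*smallest* best subset, so subset size is part of the ranking key, not a
penalty term mixed into the score.

**Perturbation (decimation).** When the best of the ranking has been flat for
`perturbation_patience` (default 10) consecutive generations, only the
strongest individual survives and the rest of the population is regenerated
randomly. For the binary stage "flat" tracks the full ranking key — best score
*and* best-ever subset size — because the score routinely saturates at AUC 1.0
while the search is still shrinking the subset; triggering on score alone
would fire a restart in the middle of that descent and destroy the elite pool.

**Training counts.** Every individual of every generation is evaluated anew —
no fitness caching by default (a `cache` flag exists) — so the audited counter
equals `population_size * generations` exactly, and elites re-prove their
fitness under the same deterministic protocol. The top ten models are the best
*distinct canonical* configurations seen anywhere in the run, not only in the
final generation: elitism makes the final generation a subset of the best-ever
archive anyway, and the archive is robust to a decimation landing on the last
generation.

## The feature stack

Six catalogued feature groups feed the ensembles, each computed per breast and
concatenated left-then-right:

| group | length | content |
|---|---|---|
| `fractals_wavelets_8ltp` | 384 | 3 fractals × 8 wavelets × 8 LTP spectra × 2 breasts |
| `fractals_8ltp` | 48 | 3 fractals × 8 LTP spectra × 2 breasts |
| `glcm` | 48 | 6 descriptors × 4 directions × 2 breasts |
| `fractals_2ltp_glcm` | 60 | 3 fractals × spectra {0, 4} × 2 breasts + GLCM |
| `fractals_3ltp` | 18 | 3 fractals × spectra {0, 3, 6} × 2 breasts |
| `glcm_8ltp` | 148 | 100 LTP histogram features + GLCM |

**GLCM.** Masked temperatures are min–max quantized per breast to 256 gray
levels (per-breast scaling removes absolute-temperature offsets between
patients); pixel pairs at distance 1 in the four standard directions, with
both pixels inside the mask, are counted into a symmetric normalized
co-occurrence matrix, from which contrast, dissimilarity, homogeneity, energy,
correlation and the angular second moment are taken. A constant ROI has one
occupied level: contrast 0, energy 1, and correlation defined as 0.

**LTP spectra.** Each interior pixel's 8-neighbourhood is ternary-coded
against a dead-zone threshold `t` (default 0.1 °C, a typical thermal-camera
sensitivity; the value is configurable because cameras differ): +1 above
center + t, −1 below center − t, 0 otherwise. Spectrum *k* collects pixels
with exactly *k* codes of +1, so the nine spectra partition the interior;
"8 LTP" uses spectra 0–7. The 100 histogram features of `glcm_8ltp` are the
normalized 25-bin histograms of the packed upper- and lower-polarity codes
(2 × 25 per breast) — the construction that reproduces the catalogued count
exactly; the bin width is the only free choice and is exposed.

**Fractal estimators.** Higuchi's curve-length dimension (k_max = 8),
Petrosian's sign-change dimension, and the Hurst exponent by rescaled-range
analysis over dyadic windows ≥ 8. They are one-dimensional, so 2-D maps are
flattened row-major after cropping to the bounding box of the masked interior.
Degenerate inputs return fixed sentinels instead of non-finite values:
Higuchi 1 (a smooth line), Petrosian 1 (its exact value at zero sign changes),
Hurst 0.5 (uncorrelated noise) — empty spectrum maps are constant series and
take exactly these values.

**Wavelet–fractal composites.** Each spectrum map (0–7) is decomposed one
level with each Daubechies family db1–db8 — "8 wavelets" is read as eight
families, the only reading consistent with the 3 × 8 × 8 × 2 = 384 product —
and the three estimators are applied to the flattened approximation band.
The transform is separable, periodized, and uses the standard published
scaling filters; odd dimensions are padded by edge replication. Periodization
maps a constant map to a constant band, so flat inputs stay flat.

## Numerical choices

- **Solver termination floor.** The SMO termination tolerance actually passed
  to the optimizer is `max(tolerance, getOption("thermoga.tol_floor", 1e-5))`.
  Polynomial-kernel configurations with tolerance ≤ 1e-6 cannot reach their
  KKT gap on small non-separable problems (the kernel values are unbounded)
  and burn the solver's fixed internal iteration budget, three orders of
  magnitude slower per fit, without changing the classifier at reported
  precision. The genome, the canonical form and the 540,560 grid count keep
  the configured tolerance; only the stopping criterion is bounded.
- **AUC** is computed by the rank (Mann–Whitney) formula with midrank ties —
  exact, and far cheaper than ROC-object construction inside a loop that runs
  18,200 times (it is cross-checked against pROC in the tests).
- **Ties** in population ranking are resolved by stable sort, hence by
  assembly order (elites first, then crossover, ...), making runs
  bit-reproducible for a fixed seed. All randomness derives from one run-level
  seed via fixed per-stage offsets.
- **Percentile baseline** scores columns with the closed-form two-class ANOVA
  F statistic (identical to `aov`, verified in tests) and keeps the top
  `ceiling(percentile * d)`.

## The synthetic generators

Real thermography archives cannot be bundled, so two seeded generators provide
inputs with the statistical structure the method assumes. `synth_roi_pairs()`
emulates a balanced static-thermography screening set: 64×64 ROIs at a 33 °C
baseline with 0.1 °C Gaussian sensor noise; `cancer` exams add a 2-D Gaussian
hot spot (default amplitude 2 °C, radius 8 px) on one random breast —
consistent with the physiological contrast between vascularized lesions and
healthy tissue. `synth_feature_table()` draws class-conditional Gaussian
features with a known informative subset shifted by a configurable effect
size (default 1.5 pooled standard deviations over 10 of 50 columns at
160 exams).

What these generators do *not* emulate matters for interpreting green tests:
no spatial correlation of sensor noise, no anatomical asymmetry between
healthy breasts, no registration error, no dependence among feature columns.
Passing the recovery benchmark therefore shows that the evolutionary machinery
optimizes what it is pointed at — not that the pipeline reaches any particular
accuracy on clinical data.

## Problem sizes used by the checks

The bundled verification uses a 60-exam, 18-feature synthetic table for the
full-budget audit run (the smallest catalogued group size, enough for a
stratified 70/30 split with 4-fold inner CV), 32×32 ROIs for the feature-stack
dimensionality checks, and the 160×50 recovery benchmark above with a reduced
evolutionary budget (populations of 40 for 10 + 20 generations, quotas scaled
proportionally from the defaults) across five seeds.

One behaviour of that reduced benchmark is worth stating plainly: with ten
informative columns at effect size 1.5 the classes are separated by ~4.7
pooled standard deviations, so the inner-CV AUC of most reasonable masks is
exactly 1.0. Subset minimality then only acts through the tie-break, which
prunes noise columns at well under a bit per generation: at this budget the
returned masks still retain noise columns alongside the informative ones,
and a longer generation budget continues the descent. A saturated fitness
carries no gradient — on strongly separable data the subset-size tie-break,
not the AUC, is the active selection pressure, and it needs generations in
proportion to the number of noise bits to shed.

## Limitations

- ROI segmentation is out of scope; inputs are pre-segmented matrices.
- The base classifier is fixed to the nu-SVM; the bucket-of-models stage has
  no hook for other estimators.
- The two stages share one split; nested resampling of the whole pipeline
  (which would cost a multiple of the 18,200 trainings) is not attempted.
- Holdout metrics at 60–160 exams carry large sampling variance; the percent
  values are reported to two decimals for table compatibility, not because
  the third digit is meaningful.
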