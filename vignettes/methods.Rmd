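---
title: "Unsupervised extraction of periodic genes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised extraction of periodic genes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcufe)
```

## The model

`pcufe` treats the identification of periodically expressed genes as an
outlier problem in a low-dimensional gene embedding, not as a curve-fitting
problem. Three working assumptions drive the pipeline:

1. **Oscillating genes co-vary.** A coherent set of periodic genes, whatever
   their waveform, dominates a small number of principal components when
   genes (rather than samples) are embedded. The PC *loadings* then inherit
   the temporal waveform, and the PC *scores* place each gene by amplitude
   and phase of its participation.
2. **Periodicity shows up as rotation.** If a pair of loadings carries an
   oscillation, its centred 2-D trajectory over time closes into an orbit
   around the origin. The winding number counts those rotations without any
   notion of period length or waveform, which is what makes the procedure
   unsupervised: the only assumption is *some* periodicity.
3. **Null scores are approximately Gaussian.** Genes without structure
   receive near-isotropic, small scores; summing their squared standardized
   scores over the selected components gives an approximately chi-squared
   statistic, so an upper-tail P-value and Benjamini–Hochberg (BH) control
   turn "far from the origin in the score plane" into a calibrated
   selection.

Assumption 3 is a working approximation, not a theorem: PC scores are
unit-norm eigenvector coordinates, and the signal genes themselves violate
Gaussianity (that is the point). The BH-adjusted chi-squared tail is used as
an outlier *ranking* with an interpretable threshold, in the spirit of the
method as practised.

## Pipeline and tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `k` | `embed_genes` | min(N, M) capped at 10 | components retained; winding only inspects the leading ones |
| `k_max` | `winding_matrix` | 4 | rank cap for loading pairs; trailing components are noise-dominated and their orbits are not limit cycles |
| `mode`, `w_min` | `select_pc_set` | `best_pair`, 0.75 turns | either the single strongest-winding pair, or all components in any pair with \|W\| ≥ `w_min` |
| `alpha` | `extract_features` | 0.01 | BH-adjusted significance level (strict `<`); 0.05 is the common choice for shorter, noisier series |
| `threshold` | `integrate_counts` | — | minimum occurrence count (inclusive) across experiment-level selections |
| `T` | `make_periodic_basis` | — | comparator period in time-point units; 12 for a 36-point/3-cycle series, 8 for a 16-point/2-cycle series |
| `A`, `ensembles` | `run_benchmark` | 1:6, 100 | disturbance amplitude sweep and replicates of the synthetic benchmark |

No numeric threshold for "exhibits a limit cycle" is inherent to the method;
`w_min = 0.75` turns (three quarters of a rotation over the whole series)
was fixed once as a conservative default and is exposed as a parameter.
Time points are treated as an ordered integer grid j = 1..M throughout; real
clock times travel only as labels.

## Numerical choices

* **Normalization.** Per-sample centring and scaling uses the population
  divisor N, matching the (1/N)Σxᵢⱼ² = 1 convention exactly; no row
  centring or scaling is applied afterwards. Zero-variance columns are an
  error, named by column.
* **Decomposition route.** Thin SVD of X; scores are left singular vectors,
  λₖ the squared singular values, loadings vₖ = Xᵀuₖ. Identical to the
  Gram-matrix eigen route (asserted in tests to 1e−8) but tractable at
  N = 10⁴. Contribution ratios divide by the total variance over *all*
  components, so retained fractions only sum to 1 at full rank.
* **Sign convention.** Eigenvector signs are arbitrary; each component is
  flipped so its largest-magnitude loading entry is positive. Winding
  numbers and the chi-squared statistic are sign-invariant, so this affects
  only reproducibility of printed output across platforms.
* **Winding step angle.** The increment is the standard signed planar angle
  Δθ = atan2(v×v′, v·v′), bounded by |Δθ| ≤ π. A literal reading of the
  usual shorthand "cos θ × sign of the cross product" does not integrate to
  turns; the atan2 form is the quantity that counts rotations. A centred
  point exactly at the origin leaves the angle undefined and is reported as
  an error with its time index.
* **Score standard deviation.** σₖ is the population root-mean-square of the
  score column about zero. Score columns are unit-norm, so σₖ = 1/√N and
  the statistic reduces to N·Σₖuₖᵢ²; both forms are computed and asserted
  equal in tests. When the embedded matrix is column-centred the scores also
  have zero mean, making this the ordinary population SD.
* **BH adjustment** delegates to `stats::p.adjust(method = "BH")` behind a
  validating wrapper; a brute-force step-up oracle cross-checks it in the
  test suite.
* **Comparator fit P-value.** Per-gene OLS on the two quadrature regressors
  f(t), f(t+T/4) (or the centred selected loadings) uses the overall F-test
  against the intercept-only model. Per-coefficient t-tests were rejected
  because the two coefficients jointly encode amplitude and phase; a gene is
  "periodic" if the pair explains variance, regardless of phase. Constant
  genes get F = 0, P = 1; numerically exact fits get P = 0. All genes share
  one QR factorisation of the design, which is the same math as 10⁴
  individual `lm()` calls at a small fraction of the cost (cross-checked
  against `lm` in tests).
* **Square/triangle templates.** The square wave takes the value 0 at its
  zero crossings (detected on the phase grid, not on floating-point
  `sin` round-off), preserving odd symmetry; the triangle wave is
  (2/π)·asin(sin(2πt/T)), which satisfies all three symmetry identities
  f(t+T) = f(t), f(T/4−t) = f(T/4+t), f(t+T/2) = −f(t) exactly on and off
  the grid, with unit amplitude.
* **Tie-breaking.** `select_pc_set` resolves winding ties toward the
  lexicographically smallest pair; `rank_equal_count` breaks P-value ties by
  larger F, then input order; K-means labels are canonicalized by centroid
  angle in 2-D. All purely for determinism.

## The synthetic generator

`generate_synthetic()` emulates a periodic-but-non-sinusoidal regime: two
quadrature basis signals of period 25 over four periods (M = 100), each
disturbed by periodic uniform noise of amplitude A (25 independent draws,
tiled, so the disturbed signals remain *exactly* periodic), with the cosine
branch orthogonalized against the sine branch; 100 signal genes mix the two
at uniform random phases; 9900 noise genes are uniform on [−1, 1]; every
gene is divided by its population SD over time (the mean is deliberately not
subtracted — the stored values follow the generating formula literally).
Draws occur in a fixed order (phases, sine disturbance, cosine disturbance,
noise matrix), so one seed determines the data set. Defaults are the
stated study conditions; sizes are configurable only for desk-scale tests.

What this emulates: a strongly driven oscillation whose waveform departs
arbitrarily far from a sinusoid while remaining periodic, against a white
background. What it does **not** emulate: temporal autocorrelation in the
background, amplitude heterogeneity across signal genes, missing values,
probe-level replication, or drift — so passing the benchmark shows
robustness of *waveform-free detection*, not robustness to every artefact of
real microarray series.

Two structural facts about the benchmark surfaced by the test suite are
worth knowing. First, the null F-test P-values of the regression comparator
are exactly uniform, so BH at 0.01 with ~100 discoveries admits about one
false discovery per data set on average; "zero noise genes selected" holds
for integer-rounded ensemble averages, not per ensemble. The projection
route's null P-values are sub-uniform (the signal genes absorb most of each
score column's unit norm), which is why its confusion matrix is almost
always exactly perfect — almost: with 9900 nulls, the top-ranked null gene
crosses the BH cutoff marginally in roughly one ensemble per hundred, which
disappears at integer precision in ensemble averages. Second, basis-shape
recovery (regressing the realized periodic signals on the first two
loadings with R² > 0.99) is a property of the *signal subspace*, which is
exactly rank 2; on the full matrix the isotropic noise bulk perturbs the
loading plane by a few percent of variance without affecting gene
selection.

## Clustering of extracted genes

Phase structure among extracted genes is examined in the selected score
plane. `kmeans_best_of` is best-of-restarts `stats::kmeans` (the standard
meaning of `nstart`): the minimal within-cluster-SS solution over the
restarts; a literal vote-over-runs consensus is intentionally not
implemented. `gmm_bic_select` delegates to `mclust::Mclust` over its default
covariance-model alphabet and reports BIC in the higher-is-better
convention; exact parity with any particular mixture package's model list is
out of scope, so cluster *counts* from different alphabets should be
compared through the cross-tabulation (`crosstab`), not taken as canonical.

## Problem sizes used by the shipped checks

The default test suite runs the benchmark at full generator size (10⁴ × 10²)
with 10 ensembles per amplitude, and the parameter-recovery and phase-ring
properties over 5 seeds; unit tests use matrices of tens to hundreds of
genes. `scripts/acceptance.R` re-runs the 6 × 10-ensemble benchmark from a
caller-supplied seed. The 100-ensemble configuration is available through
`run_benchmark(ensembles = 100)` or the `benchmark` CLI subcommand.

## Known limitations

* Winding numbers separate smooth, coherent orbits from noise; for an
  i.i.d.-random loading trajectory the step angles are uniform on (−π, π)
  and W performs a zero-drift random walk with SD √((M−1)/3)/2 turns, so a
  single |W| threshold has limited power against worst-case noise on long
  series. In practice only the leading components — whose loadings are
  smooth by construction — are inspected (`k_max`), which is the regime
  where the statistic is informative.
* The chi-squared null is approximate; the selection threshold should be
  read as a calibrated ranking cut, not an exact error rate. The BH step-up
  is applied to these approximate P-values.
* The statistic N·Σₖuₖᵢ² grows with the panel size: outlier extraction needs
  a large background of non-outlier genes to push genuine outliers into the
  chi-squared tail. On a few hundred genes the same signal genes separate
  cleanly in rank but may not clear an absolute BH cut at α = 0.01 —
  transcriptome-scale input is the intended regime, and desk-scale examples
  should be read through ranks, not through the absolute threshold.
* Replicate probes are kept distinct end to end; mapping probes to gene
  symbols (and any cross-platform harmonization before `integrate_counts`)
  is the caller's responsibility via a plain two-column join.
* Masking time points re-applies per-sample normalization on the survivors;
  selections before and after masking are therefore not nested.
* The series-matrix reader handles the tab-separated dialect with `!`
  metadata and begin/end table markers; it does not fetch anything from GEO.
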