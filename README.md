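# pcufe — PCA-based unsupervised feature extraction for periodic expression time courses

`pcufe` identifies periodically expressed genes in gene × time-point
expression matrices **without specifying the period or a template waveform**.
It is aimed at transcriptome time courses such as the yeast metabolic cycle
(YMC) or cell-division-cycle (YCDC) experiments, where the question is
"which genes oscillate?" rather than "which genes match this sinusoid?".

## The method

Given an expression matrix *X* (N genes × M time points), each column is
first normalized so that (1/N)Σᵢ xᵢⱼ = 0 and (1/N)Σᵢ xᵢⱼ² = 1. PCA is then
run in the *gene-embedding* orientation: the k-th PC **score** uₖ (one
coordinate per gene) is the eigenvector of the Gram matrix XXᵀ
(XXᵀuₖ = λₖuₖ), and the k-th PC **loading** vₖ = Xᵀuₖ (one coordinate per
time point) is the matching eigenvector of XᵀX, with ‖vₖ‖ = √λₖ. The
computation goes through the thin SVD of X, so the N×N Gram matrix is never
formed.

Periodic structure is detected on loading *pairs*: the centred trajectory
(vₖⱼ − ⟨vₖⱼ⟩, vₖ′ⱼ − ⟨vₖ′ⱼ⟩), j = 1..M, traces a closed orbit (a limit
cycle) when the pair carries an oscillation. The **winding number**

  W(M−1) = Σⱼ Δθⱼ,ⱼ₊₁ / 2π,  Δθ = atan2(vⱼ × vⱼ₊₁, vⱼ · vⱼ₊₁)

counts signed rotations of that orbit about the origin in turns; |W| ≈ the
number of oscillation periods the series spans, whatever the waveform. The
pair (or set) of components with the strongest winding becomes the
extraction set Ω.

Outlier genes along Ω are extracted with a chi-squared statistic under the
working assumption of Gaussian null scores:

  Pᵢ = P[ χ²_{|Ω|} > Σ_{k∈Ω} (uₖᵢ/σₖ)² ]

with σₖ the population SD of the k-th score column. P-values are adjusted by
the Benjamini–Hochberg step-up criterion and genes with adjusted P < α
(typically 0.01 or 0.05) are reported. Because this ranks genes by the *size
of their projection* onto the oscillating subspace — not by correlation with
a fixed template — it keeps genes whose waveform is non-sinusoidal, whose
period is a harmonic of the dominant cycle, or whose profile carries extra
non-periodic structure.

The package also provides the standard comparator (per-gene OLS fits to
sinusoidal/square/triangular waves or to the selected loadings, ranked by
overall F-test P), integration of selections across experiments by
occurrence counts, phase clustering of extracted genes (best-of-restarts
K-means and BIC-selected Gaussian mixtures), a reader for the GEO
series-matrix dialect, and a fully specified synthetic benchmark.

## Worked example

Plant 25 cyclic genes (period 12, random phases) among 475 noise genes over
36 time points — three full cycles:

```r
library(pcufe)
set.seed(10)
t <- 1:36
phase <- runif(25, 0, 2*pi)
vals <- matrix(rnorm(500*36), 500, 36)
for (i in 1:25) vals[i,] <- 4*sin(2*pi*t/12 + phase[i]) + rnorm(36, sd = 0.5)
x <- normalize_samples(expression_matrix(
  vals, gene_ids = c(sprintf("cyc_%02d", 1:25), sprintf("bg_%03d", 1:475))))

e <- embed_genes(x, k = 4)
#> gene_embedding: 500 genes, 36 time points, 4 components
#> contributions (%): 17.8, 15.6, 2.9, 2.8

wm <- winding_matrix(e, k_max = 4)
#> winding_matrix (k_max = 4), W in turns:
#>        PC1    PC2    PC3    PC4
#> PC1     NA -2.919 -0.864  0.021
#> PC2  2.919     NA  0.820  0.967
#> ...
omega <- select_pc_set(wm, mode = "best_pair")   # {1, 2}

extract_features(e, omega, alpha = 0.01)
#> selection_result: 25 of 500 genes selected (omega = {1,2}, BH-adjusted P < 0.01)
```

The PC1/PC2 loading pair winds |W| ≈ 2.92 ≈ 3 turns — three periods detected
with no period supplied — and the χ²/BH selection recovers exactly the 25
planted genes. On real data the same pipeline is one call:
`cmd_extract(list(input = "GSE3431_series_matrix.txt", out_dir = "out"))`,
or from a shell via `inst/scripts/pcufe extract --input ... --out out`.

### The synthetic benchmark

`run_benchmark()` generates data sets with two orthogonalized periodic basis
signals (period 25, four periods), 100 signal genes with uniform random
phases, 9900 uniform-noise genes, and periodic uniform disturbance of
amplitude A added to the basis; both extraction routes are scored against
the ground-truth labels at BH-adjusted P < 0.01. Projection-based extraction
stays at 100% accuracy (integer-rounded averaged confusion
[[9900, 0], [0, 100]]) for every A in 1..6, while the sensitivity of
sinusoidal-regression extraction decays from 1.0 at A = 1 to ~0.3 by A = 5–6
as the true waveform departs from the fitted sinusoid.

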