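# leafgwas

Multivariate linear mixed-model GWAS of leaf shape for clonally replicated
F1 tree crosses.

Leaf shape is hard to reduce to one number. A faithful multivariate
description is the set of *regular polar radii* — distances from the leaf
centroid to its margin at equally spaced angles. Because poplar leaves are
nearly bilaterally symmetric, a moderate number of right-side radii
(spanning −π/2 to π/2) represents the whole outline. `leafgwas` implements
the analysis chain that takes scanned leaf images and F1 SNP genotypes from
a randomized complete block design (RCBD) of clones to a genome scan of
those multivariate shape phenotypes:

* **Phenotyping** — contour extraction from rasters, orientation
  normalization, classic size traits (L, W, W1/3, W1/2, W2/3, A, L/W) and
  the RD360/RD61/RD16/RD11/RD09/RD06 polar-radius sets.
* **Genotype QC** — F1 segregation-type classification (aa×ab, aa×bc,
  ab×aa, ab×cc, ab×ab), chi-square Mendelian filtering (p > 0.01),
  missingness filtering (< 10%), and sliding-window LD pruning
  (window 25, step 2, r² > 0.7) to count independent tests.
* **Association** — REML variance components on the full-sib clone kinship
  (A = 0.5 + 0.5 I), for one trait (profile likelihood) or t traits
  (EM with spectral reduction), and the multivariate F test of
  `M Vec(B) = 0` with q = (g−1)·t numerator and t(n−p) denominator degrees
  of freedom under the model

  ```
  Y = XB + ZG + E,   Vec(G) ~ N(0, V_G ⊗ A),   Vec(E) ~ N(0, V_E ⊗ I)
  ```

* **Post-processing** — genomic inflation factor λ_GC (median chi-square
  rule), genomic control, Bonferroni thresholds on the pruned marker count,
  per-SNP variance explained (1 − RSS/RSS₀), significant-region splitting,
  Manhattan/QQ plots.
* **Synthetic data** — Mendelian F1 crosses with Haldane recombination,
  RCBD phenotypes drawn exactly from the model above, and parametric leaf
  silhouettes with analytic ground truth, so the whole pipeline is testable
  without any field or sequencing data.

The package is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` on results.

## Worked example

Simulate a cross and trial at desk scale, QC the SNPs, and scan:

```r
library(leafgwas)

cross <- simulate_cross(cross_config(
  n_clones = 80, n_chromosomes = 4, snps_per_chromosome = 50, seed = 1))
phen  <- simulate_rcbd_phenotypes(cross, trial_config(seed = 2))

records <- qc_segregation(cross)          # per-SNP type, chi2, p, missing
kept    <- filter_snps(records, cross)    # Mendelian + missingness filter
pruned  <- ld_prune(kept)                 # window 25, step 2, r2 > 0.7

scan <- run_scan(phen, kept, m_independent = pruned$n_independent)
glance(scan)
```

which prints (seed-for-seed reproducible):

```
# A tibble: 1 x 7
  n_snps n_traits lambda_gc p_threshold m_independent n_significant n_skipped
   <int>    <int>     <dbl>       <dbl>         <int>         <int>     <int>
1    197       11      1.15    0.000581            86             0         0
```

197 of the 200 simulated SNPs pass QC and are testable; LD pruning of the
kept set leaves 86 independent markers, so the genome-wide threshold is
0.05/86 ≈ 5.8e-4; the inflation factor of the null scan is close to 1; and,
with no QTL simulated, no SNP is significant. `plot_manhattan(scan)` and
`plot_qq(scan)` draw the usual summaries, and `tidy(scan)` returns the
per-SNP table (F, p_raw, p_gc, pve, region assignments).

The measurement side works the same way from images:

```r
leaf <- render_leaf(leaf_shape_params("parametric-leaf", a = 60, b = 40))
m    <- measure_leaf(leaf, radii = c("RD360", "RD11"))
m$traits
#      L     W   W13   W12   W23     A    LW
# 115.4  84.1  79.5  84.1  77.8  7494  1.37     (mm / mm^2)
```

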