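---
title: "Multivariate mixed-model GWAS of leaf shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate mixed-model GWAS of leaf shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Leaf shape in outbred trees such as poplar is a highly polygenic trait that is
awkward to reduce to a single number. A practical description is the set of
*regular polar radii*: distances from the leaf centroid to the margin at
equally spaced angles. Because a poplar leaf is close to bilaterally
symmetric, the radii on the right half of the leaf, spanning angles
$[-\pi/2, \pi/2]$, carry nearly all the shape information; reduced sets of
$k \in \{6, 9, 11, 16, 61\}$ equally spaced right-side radii (RD06 ... RD61)
give multivariate phenotypes of manageable dimension.

`leafgwas` implements the full analysis chain for a clonally replicated F1
cross grown in a randomized complete block design (RCBD): image-based leaf
morphometrics, F1 segregation quality control and LD pruning of SNPs, and a
multivariate linear mixed-model genome scan with genomic control. A
synthetic-data generator stands in for the field trial and the sequencing so
that every stage is testable end to end.

# Models

## Phenotype model

For trait $l$ of the leaf of tree $k$ of clone $j$ in block $i$:

$$y_{ijkl} = \mu_l + B_{il} + M_{jl} + G_{jl} + e_{ijkl}$$

with fixed overall means $\mu_l$, fixed block effects $B_{il}$, fixed
genotype-class effects $M_{jl}$ of the tested SNP, random polygenic clone
effects $G_{jl}$ and residuals $e_{ijkl}$. In matrix form $Y = XB + ZG + E$
with

$$\mathrm{Vec}(G) \sim N(0,\; V_G \otimes A), \qquad
  \mathrm{Vec}(E) \sim N(0,\; V_E \otimes I_n),$$

so $\mathrm{cov}(\mathrm{Vec}(Y)) = V = V_G \otimes ZAZ' + V_E \otimes I_n$.
$A$ is the additive relationship matrix of the clones. For a single full-sib
family with unrelated, non-inbred parents every pairwise kinship coefficient
is 0.25, hence $A$ has ones on the diagonal and 0.5 elsewhere
(`kinship_fullsib()`); its spectrum is closed-form (one eigenvalue
$(1+c)/2$, the rest $1/2$).

## The association test

Each SNP contributes reference-coded genotype-class columns to $X$
($g$ classes give $g-1$ columns; F1 segregation types yield $g \in \{2,3,4\}$
heterogeneous classes, so classes are unordered indicators, not dosages).
The null hypothesis "no SNP effect on any trait" is $M\,\mathrm{Vec}(B) = 0$
where $M$ selects all genotype-class coefficients across all $t$ traits
($q = (g-1)t$ rows), tested with

$$F = \frac{1}{q}\,(M\mathrm{Vec}(\hat B))'\,
      \big[M\,\mathrm{cov}(\mathrm{Vec}(\hat B))\,M'\big]^{-1}\,
      (M\mathrm{Vec}(\hat B))$$

on $q$ and $t(n-p)$ degrees of freedom. The per-SNP variance explained is
$R^2 = 1 - RSS/RSS_0$, where both residual sums of squares are computed in
the $V^{-1}$ metric under the *same* fitted covariance, with and without the
genotype columns. This makes the comparison a pure fixed-effects one and
keeps $R^2 \in [0,1]$ by construction.

## REML estimation

Variance components are estimated by restricted maximum likelihood. The key
computational identity is that the nonzero spectrum of $ZAZ'$ equals the
spectrum of $N^{1/2} A N^{1/2}$, where $N$ is the diagonal matrix of clone
sizes. All REML and GLS quantities reduce to clone-level rotated
cross-products plus totals, so nothing of size $n \times n$ is ever formed
even though the attrition-unbalanced design makes $ZAZ'$ itself irregular.

* `reml_univariate()` profiles the restricted likelihood over the variance
  ratio $\lambda = \sigma_g^2/\sigma_e^2$ on a log grid (61 points spanning
  $e^{-18}$ to $e^{12}$) refined by Brent search; a minimum pinned at the
  lower edge is reported as the $\sigma_g^2 = 0$ boundary.
* `reml_multivariate()` runs EM-REML. At each iteration the current
  $(V_G, V_E)$ pair is simultaneously diagonalized
  ($K'V_EK = I$, $K'V_GK = \Lambda$); in that basis the model decouples into
  $t$ independent weighted least-squares problems with weights
  $d_i\lambda_a + 1$, all conditional moments of the E step are diagonal, and
  the M step is exact. The restricted log-likelihood increases monotonically;
  iteration stops when its relative change drops below $10^{-10}$ (default)
  or after 5000 iterations, with a symmetric PSD projection each step.
  At $t=1$ the EM fit agrees with the independent profile fitter to better
  than $10^{-6}$ relative, which the test suite asserts.

Narrow-sense heritability is reported as
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ from the no-SNP model. The
univariate model is sometimes written with $\mathrm{cov}(g) = \sigma_g^2 I_c$;
for a single full-sib family this differs from $\sigma_g^2 A$ only through
the constant 0.5 off-diagonal. Both fitters default to $A$ for consistency
between the univariate and multivariate scans and accept
`A = "identity"` as a switch.

## Scan strategy (P3D) and genomic control

By default the variance components are estimated **once** under the no-SNP
null model and the fitted $V$ is reused for every SNP's GLS fit and F test
(the "population parameters previously determined" shortcut). `exact = TRUE`
re-estimates the components per SNP; on small scans the two agree closely
and both modes are tested. Trees whose clone genotype is missing at the
tested SNP are dropped for that SNP only; the spectral machinery is rebuilt
per missing pattern at clone-level (c × c) cost.

The genomic inflation factor is the median-based version:
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs})/0.4549$, with each p-value
converted to its 1-df chi-square quantile. When $\lambda_{GC} > 1$ every
chi-square is divided by $\lambda_{GC}$ and converted back; deflation is
deliberately left uncorrected, and significance is assessed on the corrected
p-values only when inflation was present. The significance threshold is
$\alpha/m$ where $m$ is **always** the pruned count of independent markers
and LD blocks, never the raw SNP count. Significant SNPs of a chromosome are
split into regions at each strict decrease-to-increase switch of the
$-\log_{10}p$ sequence; ties extend the current direction (the choice is
isolated in `split_regions()`).

# The synthetic-data generator

The generator's defaults are the study conditions of a real clonally
replicated poplar F1 trial and are deliberately not tuning knobs:

* **Cross**: 163 clones, 19 chromosomes, segregation-type mix proportional to
  the published per-type SNP counts (`ref_segregation_counts()`), 3%
  genotype missingness injected completely at random (the missingness
  mechanism of real RADseq data is not modeled). Parental haplotypes are
  phased with random per-SNP allele-to-haplotype assignment and gametes
  recombine under the Haldane map function, so LD decays with map distance
  exactly as physical linkage dictates rather than being drawn from a target
  correlation matrix. Chromosomes default to 2 Morgans; synthetic physical
  positions use 1 cM = 250 kb, a Populus-like genome-to-map ratio.
* **Trial**: 3 blocks, 6 cuttings per clone per plot, survival 0.765 (the
  observed fraction of planted trees that were measured in the real trial),
  block shifts of ±0.3 SD. Trees are dropped independently; no spatial field
  structure is simulated.
* **Traits**: t = 11 standardized radius-like traits with per-trait
  $h^2 \approx 0.45$ (the published single-trait heritabilities run 40-50%)
  and equicorrelated genetic (0.95) and residual (0.85) trait correlations,
  reflecting the very strong inter-radius correlations of real leaf outlines
  (first principal component > 95% of variance).
* **Leaves**: the parametric-leaf family is a tapered ellipse with polar
  radius $r(\theta) = r_{ell}(\theta)(1+\tau_t\sin\theta)/(1+\tau_b\sin\theta)$
  about the shape origin: analytic, leaf-like (deltoid), and star-convex for
  moderate taper. Circle, ellipse and rectangle fixtures have fully
  closed-form truth; the parametric leaf's truth (centroid, radii, chords) is
  evaluated on an 8192-vertex analytic polygon whose discretization error is
  far below pixel scale. Synthetic leaves carry no petiole.

What passing tests do **not** show about real data: scanner artefacts,
petioles, lobed or damaged leaves, informative missingness, genotyping error,
population structure beyond one full-sib family, and spatial field trends are
all outside the generator, so the validation bounds speak to the algorithmic
pipeline, not to image quality in the field.

## Power-study QTL

The power comparison plants a pleiotropic *shape* QTL: a $\sin\theta$
contrast across the radius angles (tip radii longer, base radii shorter, side
radii untouched) with a between-class difference of 0.3 genetic SD per trait.
This direction is orthogonal to overall size and therefore nearly invisible
to any single radius, while the multivariate test, which whitens by the
strongly correlated $(V_G, V_E)$, concentrates it into a low-variance
direction. This is the configuration in which joint modeling of the radii
genuinely pays off, and it was fixed before any power was measured.

# Numerical choices and degenerate inputs

* **Binarization**: Otsu's threshold on grayscale input; exact 0/1 images
  pass through. Foreground is assumed bright (the renderer's convention) with
  a `foreground = "dark"` switch for scans.
* **Contours**: EBImage's 8-connected boundary chains are pushed half a pixel
  along the outward normal (the true edge lies between foreground and
  background pixel centers) and lightly smoothed with a 3-point circular
  moving average to suppress staircase ripple; both corrections are below
  leaf-scale curvature.
* **Radii**: rays are intersected exactly with the boundary polygon
  (equivalent to linear interpolation between the bracketing boundary
  points). A ray crossing the boundary more than once takes the farthest
  intersection and sets a `non_star_convex` audit flag. The 1-degree grid
  anchors $\theta = 0$ at the leaf's right; reduced sets interpolate at the
  exact angles $-\pi/2 + (j-1)\pi/(k-1)$, which is why RD09's 22.5-degree
  grid is not snapped to the 1-degree grid.
* **Orientation**: principal axis from second-order area moments (Green's
  theorem closed forms); outlines with a principal moment ratio below 1.05
  are only centered and flagged `axis_ambiguous`. The tip (extreme farthest
  from the centroid along the axis) goes to +y, with a relative tolerance so
  perfectly symmetric outlines are stable under repeated normalization.
* **QC**: the Pearson chi-square against the expected ratio uses observable
  offspring classes; the 1:1 types whose four gametic combinations collapse
  to two observable classes are tested as two-class markers. A pass requires
  p > 0.01, missingness < 10%, and a ratio in {1:1, 1:2:1, 1:1:1:1}.
  Fully informative het x het crosses (1:1:1:1) are classified and testable
  even though the five tabled types do not include them; the simulator only
  generates the five tabled types.
* **LD coding**: two-class SNPs 0/1 by the informative parent's transmitted
  allele; `abxab` 0/1/2 by dosage; four-class SNPs 0/1 by the first parent's
  transmitted allele. Zero-variance pairs return $r^2 = 0$ with an
  `undefined` attribute. Pruning removes, from the worst offending pair in
  the window, the SNP with more missing data, then the later position.
* **GLS**: `gls_fit()` is the dense reference implementation used for worked
  instances and oracle tests; scans use the spectral path, and the test suite
  asserts exact agreement between the two.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as the
package's own default demonstration sizes: null-calibration scans use 150
clones and ~2000 SNPs on 19 chromosomes; power comparisons use 200 replicate
single-QTL datasets; REML recovery uses 100 replicates; geometry validation
renders 100 leaves at 300 dpi. A full scan of this size completes in about a
minute on one core because every per-SNP test costs only a clone-level
(c × c) eigendecomposition plus O(nt) transforms.

# Known limitations

* Scan-level $\lambda_{GC}$ on a *single* simulated dataset is itself noisy:
  all ~2000 tests share one realization of the clone effects and the SNPs are
  in strong LD, so $\lambda_{GC}$ varies by roughly ±0.2 across seeds even
  though the test is exactly calibrated marginally (verified over independent
  replicates). This mirrors the real-data behaviour that motivated choosing
  the radius dimension with the best genomic control; single-seed
  calibration summaries should be read with that spread in mind.
* The EM fitter rejects $t > n/2$ as ill-posed rather than regularizing.
* Region splitting is a descriptive rule on the p-value profile, not an LD
  block definition.
* PVE values from mixed models are not comparable across studies or models;
  they are reported on the percent scale for orientation only.
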