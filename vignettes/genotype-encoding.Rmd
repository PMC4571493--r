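---
title: "Data-driven genotype encodings: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven genotype encodings: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpencode)
```

## The prediction model

Genomic prediction fits the additive single-marker model

$$ y_l = \beta_0 + \sum_{i=1}^{m} \beta_i\, x_{li} + e_l $$

and, when epistasis is considered, adds pairwise interaction terms
$\alpha_{ij}\, z_{l,ij}$ where $z_{l,ij}$ is classically the product
$x_{li} x_{lj}$. Because $m \gg n$, the coefficients are shrunk: the
package's engine is ridge-regression BLUP, i.e. penalized least squares
with an unpenalized intercept and penalty $\lambda \lVert\beta\rVert^2$.
Under the mixed-model reading — marker effects iid
$N(0, \sigma^2_\beta)$, residuals $N(0, \sigma^2_e)$ — the ridge solution
at $\lambda = \sigma^2_e/\sigma^2_\beta$ *is* the best linear unbiased
predictor, which is how `ridge_reml()` chooses its shrinkage.

The quantity that makes all of this concrete is the **encoding**: the map
from the three genotype classes $\{0, 1, 2\}$ (homozygote, heterozygote,
homozygote; code 2 counts the ALT allele twice) to the real numbers
$x_{li}$ that enter the regression.

## The encoders

Let $\mathrm{trait}(i, c)$ be the training trait values of samples with
code $c$ at marker $i$, and $\bar y$ the training grand mean.

* **Fixed schemes** (`encode_traditional()`): $\{0,1,2\}$ or $\{-1,0,1\}$,
  identical at every marker. These are the baselines, and the source of
  the arbitrariness the data-driven encoders remove — e.g. heterozygote
  products are $1$ under one scheme and $0$ under the other.
* **Pure** (`fit_pure_encoding()`): $E(i, c) = \mathrm{mean}\,
  \mathrm{trait}(i, c)$ for all three classes. A target-mean encoding of
  each class.
* **Hybrid** (`fit_hybrid_encoding()`): class means for $c \in \{0, 2\}$
  but $E(i, 1) = \bar y$. The heterozygote sits between the homozygotes in
  the fixed schemes; anchoring it at the overall trait level keeps that
  intermediate role while still letting the homozygote contrast adapt per
  marker, and it removes the noisiest of the three class means.
* **Pairwise grids** (`fit_pair_encoding()`): for a pair $(i, j)$, a 3×3
  table indexed by the two codes. Corners $(a, b)$, $a, b \in \{0, 2\}$,
  are two-locus class means $\mathrm{mean}\,\mathrm{trait}(i, j, a, b)$;
  an edge cell with a heterozygote at one locus marginalises that locus
  out (cell $(1, b)$ is the single-marker class mean of marker $j$ at
  $b$); the center $(1, 1)$ is $\bar y$. The grid replaces the product
  $x_{li} x_{lj}$ as the interaction feature.

Any class (or grid cell) with no supporting training samples falls back to
$\bar y$ — consistent with the hybrid center-cell logic, and the `fallback`
column of every table makes the policy auditable.

**Leakage policy.** Encoding tables are functions of the *training* trait
values. Inside `cross_validate()` they — together with the epistasis
ranking and the model — are refit on each fold's training split and applied
read-only to the held-out split. Fitting them on all samples would leak the
prediction target into the design matrix and inflate accuracy; the
`rank_once` flag exists to reproduce such a global-ranking protocol
deliberately, and is off by default. The permutation test in the suite
(permute one fold's held-out traits, compare every fitted object bitwise)
asserts the policy mechanically.

## REML and the numerical choices

`ridge_reml()` profiles the restricted likelihood down to one dimension.
With $T$ an orthonormal basis of contrasts orthogonal to the intercept and
$\Phi = T^\top X_c X_c^\top T = U \,\mathrm{diag}(\varphi)\, U^\top$, the
rotated data $\eta = U^\top T^\top y$ are independent
$N(0, \sigma^2_\beta(\varphi_i + \lambda))$. Profiling $\sigma^2_\beta$
leaves

$$ \ell(\lambda) \propto -\tfrac12 \Big( \sum_i \log(\varphi_i + \lambda)
   + (n-1) \log \sum_i \frac{\eta_i^2}{\varphi_i + \lambda} \Big), $$

maximized on a 121-point grid in $\log_{10}\lambda \in [-6, 6]$ refined by
`stats::optimize()` to tolerance $10^{-8}$ in log-λ. Hitting a bound warns
rather than errors: noiseless traits legitimately drive
$\lambda \to 10^{-6}$ and signal-free traits $\lambda \to 10^{6}$, and both
limits produce the sensible fit (interpolation, respectively the grand
mean). The final coefficients come from the centered ridge solve at
$\hat\lambda$, using the primal normal equations when $p \le n$ and the
dual identity $\beta = X_c^\top (X_c X_c^\top + \lambda I)^{-1} y_c$ when
$p > n$, so the cost scales with $\min(n, p)^3$ and the $p \times p$
cross-product is never materialized — this is what makes 2,000-pair
epistasis designs routine.

Other numerical policies, stated once:

* class means are computed with `mean()` per class, so they agree bit-for-
  bit with a brute-force enumeration;
* modal imputation (ties toward the smaller code) keeps genotypes in
  $\{0,1,2\}$ before encoding; missing genotypes are `NA`, never −1, which
  stays available as an encoding value;
* marker filters keep on boundary equality (missing rate ≤ max, MAF ≥ min,
  heterozygosity ≤ max) and report the first failing rule in the order
  missing, MAF, heterozygosity;
* trait discretization for mutual information uses `bins` (default 10)
  equal-frequency quantile bins with deduplicated breaks, so a constant
  trait occupies one bin and has MI exactly 0;
* pair ranking ties break lexicographically by marker order, making
  rankings and hence all downstream selections deterministic;
* zero-variance observed or predicted vectors score $r^2 = 0$, so
  degenerate folds complete instead of poisoning a CV mean with `NaN`;
* encoded features are not re-standardized before regression — the
  encodings' scales are part of their design.

## Mutual information and encoding combinations

For pair ranking, the interaction feature is the *product* of the two
scheme-encoded codes under one of four combinations
(E1 = ({0,1,2}, {0,1,2}) … E4 = ({2,1,0}, {2,1,0})), and relevance is the
plug-in mutual information between the product categories and the binned
trait. The products deliberately merge genotype cells — under {0,1,2} the
cells (0,1), (0,2), (1,0), (2,0), (0,0) all map to 0 — which is exactly why
the combination changes the ranking. Two facts the test suite pins down:
MI is invariant under any injective relabeling of feature values (only the
induced partition matters), and E1/E4 (or E2/E3) are related by a global
code flip yet induce *different* partitions (E1 merges the code-0 row and
column, E4 the code-2 ones), so their rankings genuinely differ. That
low agreement between combinations is the motivation for the data-driven
grid, which assigns all nine cells their own values.

`average_overlap()` compares ranked lists that need not share elements:
the mean over depths $k = 1..K$ of the shared fraction of the two top-$k$
prefixes. It is symmetric and treats pairs as unordered.

## The simulator and what passing tests show

`simulate_gp()` emulates the encoding experiments' study design: $n = 100$
samples × $m = 500$ markers by default, per-marker alternate-allele
frequency uniform on $[0.05, 0.5]$, genotypes from the Hardy–Weinberg
class probabilities, effects $\beta_1..\beta_s \sim N(0, 1)$ with the
remaining $m - s$ effects exactly zero, residuals $N(0, 1)$, and
$Y = X\beta + e$ computed on the raw codes. $s$ is the architecture dial:
$s = 5$ oligogenic, $s = 200$ polygenic. The unit effect and residual
scales are a design choice of this package; absolute $r^2$ levels depend
on them directly, so only the *directional* contrasts between encodings
are meaningful outputs of the sweep. `encoding_sweep()` runs the full
design (10 datasets per $s$, 10-fold CV, encodings sharing folds for a
paired comparison).

What the sweep reproduces robustly: the hybrid encoding beats the
traditional one on oligogenic traits (typically 8–9 of 10 datasets at
$s = 5$) and gives the advantage back on polygenic ones (traditional ≥
hybrid in 7–8 of 10 at $s = 200$). One motivating hypothesis for the
hybrid form — that the pure encoding's heterozygote class mean is too
noisy to be useful — does *not* manifest under this generator: with MAF
bounded away from 0, heterozygote classes hold ≥ ~10% of samples at every
marker, the class mean carries usable signal, and pure and hybrid perform
comparably. A generator with near-monomorphic markers or rarer classes
would likely separate them. The
simulator also omits linkage disequilibrium, population structure and
epistatic trait architectures (a deliberate non-goal), so passing sweeps
say nothing about those features of real data.

Problem sizes throughout the suite and the acceptance script — 200 random
oracle instances at $n \le 30$, 50 REML replicates at $n = 200, m = 50$,
two sweep settings of 10 datasets each — were chosen as the smallest sizes
at which the corresponding property is stable across seeds.

## Known limitations

* Pure/hybrid encodings assume one real trait; no multi-trait support.
* The MI ranking uses the product-category construction; ranking on the
  9-cell joint genotype distribution is a different (often sharper)
  statistic and is intentionally not the default, since the product is
  what the fixed-encoding epistasis model actually uses.
* `read_vcf()` targets biallelic GT-bearing VCFs; multi-ALT sites are
  skipped, not decomposed.
* REML assumes iid marker effects; no marker-specific weights or kinship
  matrices beyond $X X^\top$.
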