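# gpencode

Data-driven genotype encodings for genomic prediction.

## The problem

Genomic prediction regresses a quantitative trait on thousands of biallelic
SNP genotypes, with far more markers than samples (m ≫ n). Before any linear
model can be fit, the three genotype classes — the two homozygotes and the
heterozygote — must be mapped to real numbers. The conventional choices,
{0, 1, 2} (ALT-allele dosage) or {−1, 0, 1}, force the *same* numeric
contrast onto every marker, even though markers differ wildly in how they
associate with the trait; for multiplicative epistasis terms the choice is
even more consequential (codes (1, 1) give the product 1 under {0, 1, 2} but
0 under {−1, 0, 1}, and (0, 1) and (0, 2) both collapse to 0).

`gpencode` implements **data-driven encodings** that let each marker choose
its own numbers from the training data:

* **pure** — encode class *c* at marker *i* by the mean training trait of
  the samples carrying *c* at *i*: `E(i, c) = mean{ y_l : x_li = c }`;
* **hybrid** — class means for the two homozygotes, but the grand training
  mean for the heterozygote: `E(i, 1) = mean(y)`;
* **pairwise grids** — a 3×3 table per marker pair for epistasis features:
  corner cells are two-locus class means, edge cells marginalise the
  heterozygous locus out, and the center cell is the grand mean.

Around the encoders the package provides the standard experimental
machinery: a ridge-regression BLUP engine (`ridge_reml()`) whose shrinkage
is the REML variance-component ratio λ = σ²ₑ/σ²_β, mutual-information
ranking of all marker pairs against the discretized trait
(`rank_pairs()`, `average_overlap()`), leakage-safe k-fold cross-validation
scored by squared Pearson correlation (`cross_validate()`), a
genotype/trait simulator spanning oligogenic to polygenic architectures
(`simulate_gp()`, `encoding_sweep()`), and readers for VCF, genotype TSV
and PLINK `.raw` files. Everything user-facing is tibble-in/tibble-out,
with `tidy()`/`glance()` for fitted objects and `autoplot()` for results.

## Worked example

Simulate an oligogenic trait (5 causal markers out of 500, 100 samples) and
compare the traditional and hybrid encodings under 10-fold CV with shared
folds:

```r
library(gpencode)

sim <- simulate_gp(n = 100, m = 500, s = 5, seed = 42)

cross_validate(sim$geno, sim$pheno, encoding = "traditional012",
               k = 10, seed = 1)
#> <cv_report> 10-fold CV, encoding = traditional012, model = reml
#>   mean r2 = 0.2559

cv <- cross_validate(sim$geno, sim$pheno, encoding = "hybrid",
                     k = 10, seed = 1)
cv
#> <cv_report> 10-fold CV, encoding = hybrid, model = reml
#>   mean r2 = 0.3779
```

On this oligogenic trait the hybrid encoding lifts the mean squared
correlation between predicted and observed trait from 0.26 to 0.38. The
per-fold detail and the fitted encoding are ordinary tibbles:

```r
tidy(cv)                     # fold, n_test, r2  (10 rows)
fit_hybrid_encoding(sim$geno, sim$pheno)
#> # A tibble: 500 x 5
#>   marker_id    e0    e1    e2 fallback
#> 1 m0001      2.17  3.41  4.67     3.41
#> 2 m0002      2.19  3.41  3.73     3.41
#> ...
```

Every marker shares the heterozygote value 3.41 (the grand trait mean);
`e0`/`e2` are that marker's homozygote class means, and `fallback` fills
genotype classes never seen in training. The underlying mixed-model fit is
available directly:

```r
X <- apply_encoding(sim$geno, fit_hybrid_encoding(sim$geno, sim$pheno))
ridge_reml(X, sim$pheno$value)
#> <ridge_blup> 500 features; lambda = 0.709 (reml)
#>   sigma2_beta = 0.05906, sigma2_e = 0.04188
```

The full architecture sweep (`encoding_sweep(c(5, 10, 20, 50, 100, 200))`)
plus `autoplot()` reproduces the oligogenic-vs-polygenic comparison: the
hybrid encoding helps when few markers carry the signal and gives its
advantage back on polygenic traits.

A thin command-line wrapper covers the same ground from a shell
(`inst/cli/gpencode.R`):

```sh
Rscript inst/cli/gpencode.R simulate --n 100 --m 500 --s 5 --seed 1 --out sim/
Rscript inst/cli/gpencode.R cv --geno sim/genotypes.tsv \
    --pheno sim/phenotypes.tsv --encoding hybrid --k 10 --seed 1 --out run/
Rscript inst/cli/gpencode.R rank-pairs --geno sim/genotypes.tsv \
    --pheno sim/phenotypes.tsv --out ranks/
```

## Methods

See the methods vignette (`vignettes/genotype-encoding.Rmd`) for the model,
the leakage policy, numerical choices and known limitations.
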