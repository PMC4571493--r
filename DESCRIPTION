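Package: gpencode
Title: Data-Driven Genotype Encodings for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction with data-driven genotype encodings. Encodes
    biallelic SNP genotypes {0,1,2} by training-trait class means (pure and
    hybrid single-marker encodings, and a 3x3 data-driven grid for pairwise
    epistasis features), fits ridge-regression BLUP with the shrinkage chosen
    as the REML variance-component ratio, ranks epistasis pairs by mutual
    information to the discretized trait, and evaluates encoding/model
    combinations by leakage-safe k-fold cross-validation scored with squared
    Pearson correlation. Includes a genotype/trait simulator for oligogenic
    and polygenic architectures, readers for VCF, genotype TSV and PLINK
    .raw files, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
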