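# Brute-force oracles and fixture builders shared across the test files.
# The oracles deliberately use plain loops, independent of the vectorized
# implementation paths they check.

# per-class trait means by explicit looping; unseen class -> grand mean
brute_pure <- function(codes, y) {
  gm <- mean(y)
  t(vapply(seq_len(ncol(codes)), function(i) {
    vapply(0:2, function(cd) {
      sel <- codes[, i] == cd
      if (any(sel)) mean(y[sel]) else gm
    }, numeric(1))
  }, numeric(3)))
}

brute_hybrid <- function(codes, y) {
  out <- brute_pure(codes, y)
  out[, 2] <- mean(y)
  out
}

# 3x3 grid for one (i, j) pair by explicit looping
brute_pair_grid <- function(codes, y, i, j) {
  gm <- mean(y)
  grid <- matrix(NA_real_, 3, 3)
  for (a in 0:2) for (b in 0:2) {
    if (a == 1 && b == 1) {
      grid[a + 1, b + 1] <- gm
    } else if (a == 1) {
      sel <- codes[, j] == b
      grid[a + 1, b + 1] <- if (any(sel)) mean(y[sel]) else gm
    } else if (b == 1) {
      sel <- codes[, i] == a
      grid[a + 1, b + 1] <- if (any(sel)) mean(y[sel]) else gm
    } else {
      sel <- codes[, i] == a & codes[, j] == b
      grid[a + 1, b + 1] <- if (any(sel)) mean(y[sel]) else gm
    }
  }
  grid
}

# random genotype/trait instance with all ids attached
random_instance <- function(n, m, seed) {
  withr::with_seed(seed, {
    codes <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    g <- geno_matrix(codes)
    list(geno = g, codes = codes,
         pheno = pheno_tbl(sample_ids(g), round(rnorm(n), 3)))
  })
}

# grid of an encoding table as an m x 3 matrix for comparison with oracles
table_grid <- function(tab) unname(as.matrix(tab[, c("e0", "e1", "e2")]))

# direct primal ridge solve used as the dual-path oracle
ridge_primal_oracle <- function(X, y, lambda) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  drop(solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, yc)))
}

# genotypes plus a trait driven multiplicatively by one planted marker pair
planted_pair_data <- function(n, m, seed, noise_sd = 0.5) {
  sim <- simulate_gp(n = n, m = m, s = 0, seed = seed)
  codes <- unclass(sim$geno)
  y <- codes[, 1] * codes[, 2] +
    withr::with_seed(seed + 1L, rnorm(n, 0, noise_sd))
  list(geno = sim$geno, pheno = pheno_tbl(sample_ids(sim$geno), y))
}

# tiny VCF fixture (3 samples x 4 sites incl. one multi-ALT, one missing)
write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./.",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "2\t50\trs4\tT\tC\t.\tPASS\t.\tGT\t0/.\t1/0\t0/0"
  ), path)
  path
}
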