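test_that("r_squared matches hand computations and the zero-variance policy", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(3, 1, 7)),
               stats::cor(c(1, 2, 3), c(3, 1, 7))^2)
  # observed (1,2,3) vs predicted (1,2,2): Pearson r = sqrt(3)/2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.75)
  expect_equal(r_squared(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(r_squared(1, 1), "at least 2")
  expect_error(r_squared(1:3, 1:4), "lengths differ")
})

test_that("fold assignment is a seeded balanced partition", {
  ids <- sprintf("s%03d", 1:100)
  f <- make_folds(ids, 10, seed = 3)
  expect_identical(sort(unique(f$fold)), 1:10)
  expect_true(all(table(f$fold) == 10))
  expect_identical(make_folds(ids, 10, seed = 3), f)     # determinism
  expect_false(identical(make_folds(ids, 10, seed = 4), f))

  # n = 11, k = 10: nine singletons and one fold of two
  f11 <- make_folds(ids[1:11], 10, seed = 1)
  expect_identical(sort(as.vector(table(f11$fold))), c(rep(1L, 9), 2L))
  expect_error(make_folds(ids[1:5], 10, seed = 1), "at least k")
})

test_that("cross_validate equals a hand-rolled loop at fixed lambda", {
  sim <- simulate_gp(n = 30, m = 10, s = 3, seed = 14)
  g <- sim$geno
  ph <- sim$pheno
  lam <- 5
  folds <- make_folds(sample_ids(g), 5, seed = 2)
  cv <- cross_validate(g, ph, encoding = "traditional012", model = "fixed",
                       lambda = lam, k = 5, seed = 2)
  # independent loop: same folds, traditional encoding, plain ridge
  tab <- encode_traditional(g, "012")
  r2s <- vapply(1:5, function(f) {
    tr <- folds$sample_id[folds$fold != f]
    te <- folds$sample_id[folds$fold == f]
    fit <- ridge_fixed(apply_encoding(g[tr, ], tab),
                       ph$value[match(tr, ph$sample_id)], lam)
    r_squared(ph$value[match(te, ph$sample_id)],
              predict(fit, apply_encoding(g[te, ], tab)))
  }, numeric(1))
  expect_equal(cv$folds$r2, r2s)
  expect_equal(cv$mean_r2, mean(r2s))
})

test_that("mean r2 is the mean of per-fold scores and folds partition samples", {
  sim <- simulate_gp(n = 33, m = 8, s = 2, seed = 15)
  cv <- suppressWarnings(cross_validate(sim$geno, sim$pheno, k = 4, seed = 7))
  expect_equal(cv$mean_r2, mean(cv$folds$r2))
  expect_true(all(cv$folds$r2 >= 0 & cv$folds$r2 <= 1))
  fa <- cv$fold_assignment
  expect_setequal(fa$sample_id, sample_ids(sim$geno))
  expect_true(max(table(fa$fold)) - min(table(fa$fold)) <= 1)
  expect_identical(sum(cv$folds$n_test), n_samples(sim$geno))
})

test_that("no state fitted in CV depends on the held-out trait values", {
  sim <- simulate_gp(n = 40, m = 12, s = 3, seed = 16)
  ph <- sim$pheno
  k <- 4
  folds <- make_folds(sample_ids(sim$geno), k, seed = 5)
  run <- function(pheno) {
    suppressWarnings(cross_validate(sim$geno, pheno, encoding = "hybrid",
                                    model = "reml", epistasis = "datadriven",
                                    top_k = 6, k = k, seed = 5,
                                    folds = folds, keep_fold_fits = TRUE))
  }
  base <- run(ph)
  # permute the trait values of fold 1's samples only; everything fold 1
  # *fitted* (trained on the other folds) must be bitwise unchanged
  test1 <- folds$sample_id[folds$fold == 1]
  ph_perm <- ph
  idx <- match(test1, ph$sample_id)
  ph_perm$value[idx] <- withr::with_seed(6, sample(ph$value[idx]))
  perm <- run(ph_perm)
  f_base <- base$fold_fits[[1]]
  f_perm <- perm$fold_fits[[1]]
  expect_identical(f_perm$encoding_table, f_base$encoding_table)
  expect_identical(f_perm$ranking, f_base$ranking)
  expect_identical(f_perm$pair_table, f_base$pair_table)
  expect_identical(f_perm$model$coefficients, f_base$model$coefficients)
  expect_identical(f_perm$model$intercept, f_base$model$intercept)
  expect_identical(f_perm$model$lambda, f_base$model$lambda)
})

test_that("a constant trait completes with all-fold r2 of zero", {
  sim <- simulate_gp(n = 24, m = 6, s = 2, seed = 17)
  ph <- pheno_tbl(sim$pheno$sample_id, rep(1.5, 24))
  cv <- cross_validate(sim$geno, ph, encoding = "traditional012",
                       model = "fixed", lambda = 1, k = 4, seed = 1)
  expect_equal(cv$folds$r2, rep(0, 4))
  expect_equal(cv$mean_r2, 0)
})

test_that("epistasis designs have the advertised width", {
  sim <- simulate_gp(n = 36, m = 6, s = 2, seed = 18)
  folds <- make_folds(sample_ids(sim$geno), 4, seed = 2)
  for (ep in c("product", "datadriven")) {
    cv <- suppressWarnings(
      cross_validate(sim$geno, sim$pheno, encoding = "traditional012",
                     model = "fixed", lambda = 1, epistasis = ep,
                     top_k = 5, k = 4, seed = 2, folds = folds,
                     keep_fold_fits = TRUE))
    fit <- cv$fold_fits[[1]]$model
    expect_identical(length(fit$coefficients), 6L + 5L)  # m + top_k
    expect_identical(sum(grepl(":", fit$feature_ids)), 5L)
  }
})

test_that("cv reports round-trip through tidy/glance and disk", {
  sim <- simulate_gp(n = 24, m = 5, s = 2, seed = 19)
  cv <- suppressWarnings(cross_validate(sim$geno, sim$pheno, k = 3, seed = 1))
  expect_identical(tidy(cv), cv$folds)
  gl <- glance(cv)
  expect_identical(gl$mean_r2, cv$mean_r2)
  expect_identical(gl$encoding, "hybrid")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.tsv")
  write_cv_report(cv, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 3 + 1)  # header, 3 folds, summary
  expect_match(lines[length(lines)], "^mean\t")
  cfg <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_identical(cfg$encoding, "hybrid")
  expect_identical(cfg$seed, 1L)
})
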