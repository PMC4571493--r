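test_that("fixed schemes map codes uniformly", {
  tab <- encode_traditional(c("m1", "m2"), "012")
  expect_identical(table_grid(tab), matrix(rep(c(0, 1, 2), each = 2), 2))
  tab2 <- encode_traditional(c("m1", "m2"), "-101")
  expect_identical(table_grid(tab2), matrix(rep(c(-1, 0, 1), each = 2), 2))
  expect_error(encode_traditional("m1", "badscheme"))

  # identity encoding reproduces the code matrix numerically
  inst <- random_instance(12, 4, seed = 1)
  X <- apply_encoding(inst$geno, encode_traditional(inst$geno, "012"))
  expect_equal(unname(X), unname(unclass(inst$geno)) * 1.0)
})

test_that("pure and hybrid encodings match the worked class means", {
  g <- geno_matrix(matrix(c(0L, 0L, 1L, 2L, 2L), 5, 1))
  p <- pheno_tbl(sample_ids(g), c(2, 4, 6, 8, 10))
  expect_equal(table_grid(fit_pure_encoding(g, p)),
               matrix(c(3, 6, 9), 1))
  ph <- pheno_tbl(sample_ids(g), c(2, 4, 7, 8, 10))
  hyb <- fit_hybrid_encoding(g, ph)
  expect_equal(table_grid(hyb), matrix(c(3, 31 / 5, 9), 1))
  expect_equal(table_grid(fit_pure_encoding(g, ph))[, 2], 7)

  # constant trait encodes to the constant everywhere
  pc <- pheno_tbl(sample_ids(g), rep(4.2, 5))
  expect_true(all(table_grid(fit_pure_encoding(g, pc)) == 4.2))
  expect_true(all(table_grid(fit_hybrid_encoding(g, pc)) == 4.2))

  # unseen class falls back to the grand mean
  g2 <- geno_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1))
  p2 <- pheno_tbl(sample_ids(g2), c(1, 2, 3, 4))
  expect_equal(table_grid(fit_pure_encoding(g2, p2))[, 3], 2.5)

  # all-heterozygote marker: everything collapses to the grand mean
  g3 <- geno_matrix(matrix(1L, 4, 1))
  expect_true(all(table_grid(fit_hybrid_encoding(g3, p2)) == 2.5))
})

test_that("encoders agree exactly with the brute-force class-mean oracle", {
  for (sd in 1:25) {
    n <- 5L + (sd * 7L) %% 26L
    m <- 2L + (sd * 3L) %% 9L
    inst <- random_instance(n, m, seed = sd * 100)
    y <- inst$pheno$value
    expect_identical(table_grid(fit_pure_encoding(inst$geno, inst$pheno)),
                     brute_pure(inst$codes, y))
    expect_identical(table_grid(fit_hybrid_encoding(inst$geno, inst$pheno)),
                     brute_hybrid(inst$codes, y))
    pairs <- tibble::tibble(marker_i = marker_ids(inst$geno)[1],
                            marker_j = marker_ids(inst$geno)[2])
    pt <- fit_pair_encoding(inst$geno, inst$pheno, pairs)
    grid <- matrix(unlist(pt[1, paste0("e", rep(0:2, each = 3),
                                       rep(0:2, 3))], use.names = FALSE),
                   3, 3, byrow = TRUE)
    expect_identical(grid, brute_pair_grid(inst$codes, y, 1, 2))
  }
})

test_that("pairwise grid matches the six-sample worked example", {
  codes <- cbind(i = c(0L, 0L, 2L, 0L, 2L, 1L),
                 j = c(0L, 0L, 0L, 2L, 2L, 1L))
  g <- geno_matrix(codes)
  p <- pheno_tbl(sample_ids(g), c(1, 3, 5, 7, 9, 11))
  pt <- fit_pair_encoding(g, p, cbind("i", "j"))
  got <- unlist(pt[1, c("e00", "e20", "e02", "e22",
                        "e10", "e01", "e21", "e12", "e11")],
                use.names = FALSE)
  expect_equal(got, c(2, 5, 7, 9, 3, 11 / 3, 7, 8, 6))
})

test_that("pairwise grid satisfies the hybrid marginal identities", {
  inst <- random_instance(25, 6, seed = 77)
  hyb <- fit_hybrid_encoding(inst$geno, inst$pheno)
  ids <- marker_ids(inst$geno)
  pairs <- tibble::tibble(marker_i = ids[c(1, 2)], marker_j = ids[c(3, 5)])
  pt <- fit_pair_encoding(inst$geno, inst$pheno, pairs)
  for (r in 1:2) {
    hi <- hyb[hyb$marker_id == pt$marker_i[r], ]
    hj <- hyb[hyb$marker_id == pt$marker_j[r], ]
    # row 1 marginalises marker i: cells (1,0), (1,2) = E(j, 0), E(j, 2)
    expect_identical(pt$e10[r], hj$e0)
    expect_identical(pt$e12[r], hj$e2)
    # column 1 marginalises marker j: cells (0,1), (2,1) = E(i, 0), E(i, 2)
    expect_identical(pt$e01[r], hi$e0)
    expect_identical(pt$e21[r], hi$e2)
    # center = grand mean = hybrid heterozygote encoding
    expect_identical(pt$e11[r], hi$e1)
    expect_identical(pt$e11[r], mean(inst$pheno$value))
  }
  # i == j is rejected
  expect_error(fit_pair_encoding(inst$geno, inst$pheno,
                                 cbind(ids[1], ids[1])), "self-pair")
})

test_that("encodings obey permutation, label-swap and affine symmetries", {
  inst <- random_instance(20, 5, seed = 42)
  g <- inst$geno
  p <- inst$pheno

  # sample permutation leaves every table unchanged
  perm <- withr::with_seed(9, sample(n_samples(g)))
  g_p <- g[perm, ]
  p_p <- p[perm, ]
  expect_equal(fit_pure_encoding(g_p, p_p), fit_pure_encoding(g, p))
  expect_equal(fit_hybrid_encoding(g_p, p_p), fit_hybrid_encoding(g, p))

  # swapping codes 0<->2 at one marker swaps e0/e2, leaves hybrid e1 alone
  codes2 <- unclass(g)
  codes2[, 3] <- 2L - codes2[, 3]
  hyb <- fit_hybrid_encoding(g, p)
  hyb2 <- fit_hybrid_encoding(geno_matrix(codes2, sample_ids(g),
                                          marker_ids(g)), p)
  expect_identical(hyb2$e0[3], hyb$e2[3])
  expect_identical(hyb2$e2[3], hyb$e0[3])
  expect_identical(hyb2$e1[3], hyb$e1[3])

  # trait affine map y -> a y + b maps every encoding value accordingly
  a <- 2.5; b <- -3
  p_aff <- pheno_tbl(p$sample_id, a * p$value + b)
  for (fitter in list(fit_pure_encoding, fit_hybrid_encoding)) {
    t0 <- fitter(g, p)
    t1 <- fitter(g, p_aff)
    expect_equal(table_grid(t1), a * table_grid(t0) + b)
  }

  # pure and hybrid always agree on the homozygote codes
  expect_identical(fit_pure_encoding(g, p)$e0, fit_hybrid_encoding(g, p)$e0)
  expect_identical(fit_pure_encoding(g, p)$e2, fit_hybrid_encoding(g, p)$e2)
})

test_that("apply_encoding and apply_pair_encoding look values up correctly", {
  g <- geno_matrix(matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(NULL, "m")))
  tab <- encode_traditional("m", "012")
  tab$e0 <- 3; tab$e1 <- 6.2; tab$e2 <- 9
  expect_equal(unname(apply_encoding(g, tab)[, 1]), c(3, 6.2, 9))
  expect_error(apply_encoding(g, encode_traditional("other", "012")),
               "absent from encoding table: m")

  codes <- cbind(i = c(0L, 0L, 2L, 0L, 2L, 1L),
                 j = c(0L, 0L, 0L, 2L, 2L, 1L))
  gp <- geno_matrix(codes)
  ph <- pheno_tbl(sample_ids(gp), c(1, 3, 5, 7, 9, 11))
  pt <- fit_pair_encoding(gp, ph, cbind("i", "j"))
  Xp <- apply_pair_encoding(gp, pt)
  expect_identical(colnames(Xp), "i:j")
  expect_equal(unname(Xp[1, 1]), 2)    # corner (0,0)
  expect_equal(unname(Xp[6, 1]), 6)    # center = grand mean

  # empty pair list -> zero features
  empty <- fit_pair_encoding(gp, ph,
                             tibble::tibble(marker_i = character(0),
                                            marker_j = character(0)))
  expect_identical(ncol(apply_pair_encoding(gp, empty)), 0L)
})

test_that("product features reproduce the scheme-sensitivity examples", {
  g <- geno_matrix(cbind(a = c(1L, 0L, 0L), b = c(1L, 1L, 2L)))
  pairs <- tibble::tibble(marker_i = "a", marker_j = "b")
  X012 <- apply_encoding(g, encode_traditional(g, "012"))
  X101 <- apply_encoding(g, encode_traditional(g, "-101"))
  prod012 <- product_features(X012, pairs)
  prod101 <- product_features(X101, pairs)
  expect_equal(unname(prod012[1, 1]), 1)  # (1,1): 1 x 1 = 1
  expect_equal(unname(prod101[1, 1]), 0)  # (1,1): 0 x 0 = 0
  expect_equal(unname(prod012[2:3, 1]), c(0, 0))  # (0,1) and (0,2) merge
  expect_error(product_features(X012,
                                tibble::tibble(marker_i = "a",
                                               marker_j = "zzz")),
               "absent")
})
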