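#' Simulate a genotype/trait data set
#'
#' Generates `n` samples by `m` biallelic markers and an additive
#' quantitative trait. Each marker gets an alternate-allele frequency drawn
#' uniformly from `maf_range` and genotypes sampled from the
#' Hardy–Weinberg class probabilities \eqn{((1-p)^2, 2p(1-p), p^2)} for
#' codes (0, 1, 2). Marker effects \eqn{\beta_1 \ldots \beta_s} are drawn
#' \eqn{N(0, \sigma_\beta^2)} for the first `s` markers and are exactly 0
#' for the rest, so `s` controls the trait architecture: small `s` gives an
#' oligogenic trait, large `s` a polygenic one. The trait is
#' \eqn{Y = X\beta + e} on the raw \{0, 1, 2\} codes, with
#' \eqn{e \sim N(0, \sigma_e^2)}; encodings are applied only at analysis
#' time, never here.
#'
#' The defaults (100 samples, 500 markers, unit effect and residual scales)
#' are the study conditions of the encoding-comparison experiments.
#'
#' @param n Number of samples (default 100).
#' @param m Number of markers (default 500).
#' @param s Number of causal markers, `0 <= s <= m` (default 5).
#' @param sigma_beta Effect-size standard deviation (default 1).
#' @param sigma_e Residual standard deviation (default 1, `>= 0`).
#' @param maf_range Range of the per-marker alternate-allele frequency
#'   (default `c(0.05, 0.5)`).
#' @param seed Integer seed; the draw is fully reproducible from it and is
#'   applied locally (session RNG untouched).
#' @return A list: `geno` ([geno_matrix()]), `pheno` (tibble), and `truth`
#'   — a list with `beta` (tibble `marker_id`, `beta`), `residuals`,
#'   `maf`, for effect-recovery tests.
#' @export
simulate_gp <- function(n = 100, m = 500, s = 5,
                        sigma_beta = 1, sigma_e = 1,
                        maf_range = c(0.05, 0.5), seed = 1) {
  if (s < 0 || s > m) stop("`s` must be in 0..m (m = ", m, ")", call. = FALSE)
  if (sigma_e < 0 || sigma_beta < 0) {
    stop("`sigma_beta` and `sigma_e` must be nonnegative", call. = FALSE)
  }
  if (n < 1 || m < 1) stop("`n` and `m` must be positive", call. = FALSE)
  withr::with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    probs <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
    codes <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      codes[, j] <- sample(0:2, n, replace = TRUE, prob = probs[j, ])
    }
    beta <- numeric(m)
    if (s > 0) beta[seq_len(s)] <- stats::rnorm(s, 0, sigma_beta)
    e <- stats::rnorm(n, 0, sigma_e)
    y <- drop(codes %*% beta) + e
    g <- geno_matrix(codes,
                     sample_ids = sprintf("s%03d", seq_len(n)),
                     marker_ids = sprintf("m%04d", seq_len(m)))
    list(geno = g,
         pheno = pheno_tbl(sample_ids(g), y),
         truth = list(beta = tibble::tibble(marker_id = marker_ids(g),
                                            beta = beta),
                      residuals = e, maf = p))
  })
}

#' Sweep trait architectures and encodings by cross-validation
#'
#' The encoding-comparison experiment: for each number of causal markers
#' `s`, simulates `n_datasets` independent data sets and cross-validates
#' each requested encoding on every data set with *shared* folds (a paired
#' comparison). Reports the per-dataset mean r-squared.
#'
#' @param s_values Integer vector of causal-marker counts to sweep.
#' @param n_datasets Data sets per `s` (default 10).
#' @param encodings Encoding arms (default traditional \{0,1,2\}, pure and
#'   hybrid data-driven).
#' @param k CV folds (default 10).
#' @param model,lambda Passed to [cross_validate()].
#' @param n,m,sigma_beta,sigma_e Passed to [simulate_gp()].
#' @param seed Master seed; per-dataset simulation and fold seeds are
#'   derived from it.
#' @return A `gp_sweep` tibble (`s`, `dataset`, `encoding`, `mean_r2`);
#'   see [sweep_summary()] and [autoplot.gp_sweep()].
#' @export
encoding_sweep <- function(s_values, n_datasets = 10,
                           encodings = c("traditional012", "pure", "hybrid"),
                           k = 10, model = "reml", lambda = NULL,
                           n = 100, m = 500,
                           sigma_beta = 1, sigma_e = 1, seed = 1) {
  if (length(s_values) == 0L) stop("`s_values` is empty", call. = FALSE)
  n_draw <- 2L * length(s_values) * n_datasets
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_draw))
  sub_seeds <- matrix(sub_seeds, ncol = 2L)  # col 1: data, col 2: folds
  rows <- list()
  idx <- 0L
  for (si in seq_along(s_values)) {
    for (d in seq_len(n_datasets)) {
      idx <- idx + 1L
      sim <- simulate_gp(n = n, m = m, s = s_values[si],
                         sigma_beta = sigma_beta, sigma_e = sigma_e,
                         seed = sub_seeds[idx, 1])
      folds <- make_folds(sample_ids(sim$geno), k, sub_seeds[idx, 2])
      for (enc in encodings) {
        cv <- cross_validate(sim$geno, sim$pheno, encoding = enc,
                             model = model, lambda = lambda,
                             k = k, seed = sub_seeds[idx, 2], folds = folds)
        rows[[length(rows) + 1L]] <-
          tibble::tibble(s = s_values[si], dataset = d, encoding = enc,
                         mean_r2 = cv$mean_r2)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gp_sweep", class(out))
  out
}

#' Summarize a sweep as an s-by-encoding table
#'
#' Averages the per-dataset mean r-squared over data sets, one row per `s`
#' and one column per encoding.
#'
#' @param sweep A `gp_sweep` tibble from [encoding_sweep()].
#' @return A wide tibble, rows `s`, columns the encodings.
#' @export
sweep_summary <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$s, .data$encoding) |>
    dplyr::summarise(mean_r2 = mean(.data$mean_r2), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "encoding", values_from = "mean_r2")
}

#' Write simulated data to disk
#'
#' Writes the genotype TSV, the phenotype TSV and a truth-record TSV
#' (marker id, true effect) in the package's file dialects.
#'
#' @param sim A simulation result from [simulate_gp()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genotype_tsv(sim$geno, paths[["genotypes"]])
  write_phenotype(sim$pheno, paths[["phenotypes"]])
  tr <- sim$truth$beta
  writeLines(c("marker_id\tbeta",
               paste0(tr$marker_id, "\t", format_full(tr$beta))),
             paths[["truth"]])
  invisible(paths)
}
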