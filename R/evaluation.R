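#' Squared Pearson correlation
#'
#' The prediction-accuracy metric: the square of the Pearson correlation
#' between observed and predicted trait values. Defined as 0 when either
#' vector has zero variance, so degenerate folds do not poison a
#' cross-validation mean with `NaN`.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A scalar in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) return(0)
  stats::cor(observed, predicted)^2
}

#' Random k-fold assignment
#'
#' Seeded uniform partition of the samples into `k` folds whose sizes
#' differ by at most one. The seed is applied locally and does not disturb
#' the session RNG state.
#'
#' @param sample_ids Character vector of sample ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A tibble (`sample_id`, `fold`).
#' @export
make_folds <- function(sample_ids, k, seed) {
  n <- length(sample_ids)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k = ", k, " samples, got ", n, call. = FALSE)
  fold <- withr::with_seed(seed,
                           sample(rep(seq_len(k), length.out = n)))
  tibble::tibble(sample_id = as.character(sample_ids), fold = fold)
}

cv_encodings <- c("traditional012", "traditional-101", "pure", "hybrid")

fit_encoding_by_name <- function(encoding, g, pheno) {
  switch(encoding,
         "traditional012" = encode_traditional(marker_ids(g), "012"),
         "traditional-101" = encode_traditional(marker_ids(g), "-101"),
         "pure" = fit_pure_encoding(g, pheno),
         "hybrid" = fit_hybrid_encoding(g, pheno),
         stop("unknown encoding '", encoding, "'", call. = FALSE))
}

#' Leakage-safe k-fold cross-validation of an encoding/model combination
#'
#' For each fold, *everything* learned from data — the encoding table, the
#' epistasis MI ranking and pair grids, and the ridge model — is fit on the
#' training split only and applied read-only to the held-out split, which
#' is scored by [r_squared()]. The reported `mean_r2` is the arithmetic
#' mean of the per-fold r-squared values (not a pooled-prediction r²).
#'
#' With `epistasis = "product"` the design is the encoded main effects plus
#' multiplicative interaction features for the top-`top_k` MI-ranked pairs;
#' with `"datadriven"` the interaction features come from the 3x3 grid of
#' [fit_pair_encoding()] instead. The ranking is recomputed inside every
#' training fold; `rank_once = TRUE` reproduces the cheaper global-ranking
#' protocol, which reads all trait values and is therefore leaky —
#' off by default.
#'
#' @param g A [geno_matrix()]; missing genotypes are modal-imputed
#'   up front.
#' @param pheno Phenotype tibble (`sample_id`, `value`).
#' @param encoding One of `"traditional012"`, `"traditional-101"`,
#'   `"pure"`, `"hybrid"`.
#' @param model `"reml"` (variance-component shrinkage) or `"fixed"`
#'   (ridge at `lambda`).
#' @param lambda Shrinkage for `model = "fixed"`.
#' @param epistasis `"none"`, `"product"` or `"datadriven"`.
#' @param top_k Number of top MI pairs used when epistasis is on
#'   (default 2000).
#' @param bins Trait quantile bins for the MI ranking.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param folds Optional precomputed fold tibble from [make_folds()]
#'   (lets several encoding arms share folds for a paired comparison).
#' @param rank_once Rank epistasis pairs once on all samples (leaky;
#'   default `FALSE`).
#' @param keep_fold_fits Keep each fold's fitted encoding table, ranking
#'   and model in the report (for audit; default `FALSE`).
#' @return A `cv_report` object; see [tidy.cv_report()].
#' @export
cross_validate <- function(g, pheno,
                           encoding = "hybrid",
                           model = c("reml", "fixed"),
                           lambda = NULL,
                           epistasis = c("none", "product", "datadriven"),
                           top_k = 2000, bins = 10,
                           k = 10, seed = 1,
                           folds = NULL,
                           rank_once = FALSE,
                           keep_fold_fits = FALSE) {
  model <- match.arg(model)
  epistasis <- match.arg(epistasis)
  encoding <- match.arg(encoding, cv_encodings)
  if (model == "fixed" && (is.null(lambda) || lambda <= 0)) {
    stop("model = \"fixed\" requires a positive `lambda`", call. = FALSE)
  }
  al <- align_genotypes(g, pheno)
  g <- impute_missing(al$geno)
  pheno <- al$pheno
  if (is.null(folds)) folds <- make_folds(sample_ids(g), k, seed)
  if (!setequal(folds$sample_id, sample_ids(g))) {
    stop("`folds` do not cover exactly the aligned samples", call. = FALSE)
  }
  k <- max(folds$fold)

  global_ranking <- NULL
  if (epistasis != "none" && rank_once) {
    global_ranking <- top_pairs(rank_pairs(g, pheno, combo = "E1",
                                           bins = bins), top_k)
  }

  fold_rows <- vector("list", k)
  fold_fits <- if (keep_fold_fits) vector("list", k) else NULL
  for (f in seq_len(k)) {
    test_ids <- folds$sample_id[folds$fold == f]
    train_ids <- folds$sample_id[folds$fold != f]
    g_tr <- g[train_ids, ]
    g_te <- g[test_ids, ]
    p_tr <- pheno[match(train_ids, pheno$sample_id), ]
    y_te <- pheno$value[match(test_ids, pheno$sample_id)]

    tab <- fit_encoding_by_name(encoding, g_tr, p_tr)
    X_tr <- apply_encoding(g_tr, tab)
    X_te <- apply_encoding(g_te, tab)

    ranking <- NULL
    pair_tab <- NULL
    if (epistasis != "none") {
      ranking <- if (rank_once) global_ranking else {
        top_pairs(rank_pairs(g_tr, p_tr, combo = "E1", bins = bins), top_k)
      }
      if (epistasis == "datadriven") {
        pair_tab <- fit_pair_encoding(g_tr, p_tr, ranking)
        X_tr <- cbind(X_tr, apply_pair_encoding(g_tr, pair_tab))
        X_te <- cbind(X_te, apply_pair_encoding(g_te, pair_tab))
      } else {
        X_tr <- cbind(X_tr, product_features(X_tr, ranking))
        X_te <- cbind(X_te, product_features(X_te, ranking))
      }
    }

    y_tr <- p_tr$value
    if (stats::sd(y_tr) == 0) {
      # degenerate training trait: mean prediction, fold scores 0
      preds <- rep(mean(y_tr), length(y_te))
      fit <- NULL
    } else {
      fit <- if (model == "reml") ridge_reml(X_tr, y_tr) else
        ridge_fixed(X_tr, y_tr, lambda)
      preds <- predict(fit, X_te)
    }
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = length(test_ids),
                                     r2 = r_squared(y_te, preds))
    if (keep_fold_fits) {
      fold_fits[[f]] <- list(encoding_table = tab, ranking = ranking,
                             pair_table = pair_tab, model = fit)
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(list(folds = folds_tbl,
                 mean_r2 = mean(folds_tbl$r2),
                 fold_assignment = folds,
                 seed = seed,
                 config = list(encoding = encoding, model = model,
                               lambda = lambda, epistasis = epistasis,
                               top_k = if (epistasis == "none") NULL else top_k,
                               bins = bins, k = k, seed = seed,
                               rank_once = rank_once),
                 fold_fits = fold_fits),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$config$k, "-fold CV, encoding = ",
      x$config$encoding, ", model = ", x$config$model,
      if (x$config$epistasis != "none")
        paste0(", epistasis = ", x$config$epistasis) else "",
      "\n  mean r2 = ", signif(x$mean_r2, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' `tidy()` returns the per-fold table; `glance()` a one-row summary.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble::tibble(mean_r2 = x$mean_r2,
                 k = x$config$k,
                 encoding = x$config$encoding,
                 model = x$config$model,
                 epistasis = x$config$epistasis,
                 seed = x$seed)
}

#' Write a CV report to disk
#'
#' Writes the per-fold TSV (fold, r2) with a trailing summary row and a
#' JSON sidecar echoing the full configuration (seed included) for
#' reproducibility.
#'
#' @param report A `cv_report`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  tab <- report$folds
  tab$r2 <- format_full(tab$r2)
  lines <- c("fold\tn_test\tr2",
             sprintf("%d\t%d\t%s", tab$fold, tab$n_test, tab$r2),
             sprintf("mean\t%d\t%s", sum(report$folds$n_test),
                     format_full(report$mean_r2)))
  writeLines(lines, path)
  jsonlite::write_json(report$config,
                       sub("\\.tsv$", "", path) |> paste0(".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
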