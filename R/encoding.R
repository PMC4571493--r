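#' Single-marker encoding tables
#'
#' An encoding table maps each genotype code \{0, 1, 2\} of each marker to a
#' real value that can enter a linear regression. It is a tibble with
#' columns `marker_id`, `e0`, `e1`, `e2` and `fallback` (the value used for
#' a genotype class never seen in training), plus a `scheme` attribute
#' naming its provenance (`"traditional012"`, `"traditional-101"`, `"pure"`
#' or `"hybrid"`).
#'
#' `encode_traditional()` builds the fixed schemes that apply the same map
#' to every marker: `"012"` keeps the codes as-is, `"-101"` maps the two
#' homozygotes to -1 and 1 and the heterozygote to 0.
#'
#' @param markers Character vector of marker ids (typically
#'   `marker_ids(g)`), or a [geno_matrix()].
#' @param scheme `"012"` or `"-101"`.
#' @return An encoding table tibble.
#' @examples
#' tab <- encode_traditional(c("m1", "m2"), "-101")
#' tab
#' @export
encode_traditional <- function(markers, scheme = c("012", "-101")) {
  scheme <- match.arg(scheme)
  if (inherits(markers, "geno_matrix")) markers <- marker_ids(markers)
  vals <- if (scheme == "012") c(0, 1, 2) else c(-1, 0, 1)
  out <- tibble::tibble(marker_id = as.character(markers),
                        e0 = vals[1], e1 = vals[2], e2 = vals[3],
                        fallback = vals[2])
  attr(out, "scheme") <- if (scheme == "012") "traditional012" else "traditional-101"
  class(out) <- c("encoding_tbl", class(out))
  out
}

# per-marker, per-code trait means; NA where a class has no samples
class_mean_matrix <- function(codes, y) {
  m <- ncol(codes)
  out <- matrix(NA_real_, m, 3)
  for (cd in 0:2) {
    sel <- codes == cd
    hit <- which(colSums(sel) > 0)
    out[hit, cd + 1L] <- vapply(hit, function(i) mean(y[sel[, i]]),
                                numeric(1))
  }
  out
}

encoding_inputs <- function(g, pheno) {
  al <- align_genotypes(g, pheno)
  codes <- unclass(al$geno)
  if (anyNA(codes)) {
    stop("genotypes contain missing values; run impute_missing() first",
         call. = FALSE)
  }
  list(codes = codes, y = al$pheno$value)
}

#' Fit data-driven single-marker encodings
#'
#' `fit_pure_encoding()` encodes genotype class `c` at marker `i` by the
#' mean trait of the training samples carrying class `c` at `i` — including
#' the heterozygote. `fit_hybrid_encoding()` keeps the class means for the
#' two homozygotes but encodes the heterozygote by the grand mean of all
#' training traits (the same value at every marker), tying it to the overall
#' trait level instead of a possibly noisy heterozygote-only mean. In both,
#' a class with no training samples falls back to the training grand mean.
#'
#' Tables are fit strictly on training data and applied read-only to test
#' data; fitting on test traits would leak the prediction target.
#'
#' @param g A [geno_matrix()] with no missing entries.
#' @param pheno Phenotype tibble aligned (or alignable) to `g`.
#' @return An encoding table tibble (see [encode_traditional()]).
#' @examples
#' g <- geno_matrix(matrix(c(0, 0, 1, 2, 2), ncol = 1))
#' p <- pheno_tbl(sample_ids(g), c(2, 4, 6, 8, 10))
#' fit_pure_encoding(g, p)    # class means 3, 6, 9
#' @export
fit_pure_encoding <- function(g, pheno) {
  inp <- encoding_inputs(g, pheno)
  gm <- mean(inp$y)
  M <- class_mean_matrix(inp$codes, inp$y)
  M[is.na(M)] <- gm
  out <- tibble::tibble(marker_id = colnames(inp$codes),
                        e0 = M[, 1], e1 = M[, 2], e2 = M[, 3], fallback = gm)
  attr(out, "scheme") <- "pure"
  class(out) <- c("encoding_tbl", class(out))
  out
}

#' @rdname fit_pure_encoding
#' @export
fit_hybrid_encoding <- function(g, pheno) {
  out <- fit_pure_encoding(g, pheno)
  out$e1 <- out$fallback[1]  # grand mean, identical across markers
  attr(out, "scheme") <- "hybrid"
  out
}

#' Fit the data-driven 3x3 grid for pairwise epistasis features
#'
#' For each requested marker pair (i, j) a 3x3 grid of real values is fit on
#' the training data, indexed (row = code at i, column = code at j):
#' the four corner cells are the mean trait over samples carrying exactly
#' those two homozygous codes; an edge cell involving the heterozygote at
#' one marker marginalises it out — e.g. cell (1, 0) is the mean trait over
#' all samples with code 0 at marker j, whatever their code at i; and the
#' center cell (1, 1) is the grand mean of all training traits. Any cell
#' with no supporting samples falls back to the grand mean.
#'
#' @param g A [geno_matrix()] with no missing entries.
#' @param pheno Phenotype tibble aligned (or alignable) to `g`.
#' @param pairs A data frame with character columns `marker_i`, `marker_j`
#'   (as produced by [rank_pairs()]), or a two-column character matrix.
#'   Pairs are stored with i before j in the matrix's column order.
#' @return A pair-encoding tibble with columns `marker_i`, `marker_j`, the
#'   nine grid cells `e00, e01, e02, e10, e11, e12, e20, e21, e22` (cell
#'   `eab` = code `a` at marker i, code `b` at marker j) and `fallback`.
#' @export
fit_pair_encoding <- function(g, pheno, pairs) {
  inp <- encoding_inputs(g, pheno)
  codes <- inp$codes
  y <- inp$y
  gm <- mean(y)
  pr <- canonical_pairs(pairs, colnames(codes))

  # marginal (single-marker) class means, used by the edge cells
  marg <- class_mean_matrix(codes, y)  # m x 3, NA when class empty
  cell_names <- paste0("e", rep(0:2, each = 3), rep(0:2, times = 3))
  grid <- matrix(NA_real_, nrow(pr), 9,
                 dimnames = list(NULL, cell_names))
  ci <- match(pr$marker_i, colnames(codes))
  cj <- match(pr$marker_j, colnames(codes))
  for (k in seq_len(nrow(pr))) {
    xi <- codes[, ci[k]]
    xj <- codes[, cj[k]]
    for (a in c(0L, 2L)) for (b in c(0L, 2L)) {
      sel <- xi == a & xj == b
      grid[k, paste0("e", a, b)] <- if (any(sel)) mean(y[sel]) else gm
    }
    for (b in 0:2) {  # row 1: heterozygote at i marginalised out
      v <- marg[cj[k], b + 1L]
      grid[k, paste0("e1", b)] <- if (is.na(v)) gm else v
    }
    for (a in c(0L, 2L)) {  # column 1: heterozygote at j marginalised out
      v <- marg[ci[k], a + 1L]
      grid[k, paste0("e", a, 1L)] <- if (is.na(v)) gm else v
    }
    grid[k, "e11"] <- gm
  }
  out <- tibble::tibble(marker_i = pr$marker_i, marker_j = pr$marker_j)
  out <- dplyr::bind_cols(out, tibble::as_tibble(grid))
  out$fallback <- gm
  class(out) <- c("pair_encoding_tbl", class(out))
  out
}

# normalize a pairs argument to a tibble(marker_i, marker_j), i before j in
# `markers` order, no self-pairs, no duplicates
canonical_pairs <- function(pairs, markers) {
  if (is.matrix(pairs)) {
    pairs <- tibble::tibble(marker_i = as.character(pairs[, 1]),
                            marker_j = as.character(pairs[, 2]))
  }
  if (!is.data.frame(pairs) || !all(c("marker_i", "marker_j") %in% names(pairs))) {
    stop("`pairs` must have columns `marker_i` and `marker_j`", call. = FALSE)
  }
  a <- as.character(pairs$marker_i)
  b <- as.character(pairs$marker_j)
  unknown <- setdiff(c(a, b), markers)
  if (length(unknown)) {
    stop("pair marker(s) absent from genotype matrix: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(a == b)) {
    stop("self-pair not allowed: ", a[a == b][1], call. = FALSE)
  }
  ia <- match(a, markers)
  ib <- match(b, markers)
  swap <- ia > ib
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- tibble::tibble(marker_i = a, marker_j = b)
  dplyr::distinct(out)
}

#' Apply an encoding table to a genotype matrix
#'
#' Replaces every genotype code by its encoded real value, producing the
#' regression design for the single-marker model. Feature ids are the marker
#' ids; sample order is preserved.
#'
#' @param g A [geno_matrix()] with no missing entries; every marker must be
#'   present in `table`.
#' @param table An encoding table from [encode_traditional()],
#'   [fit_pure_encoding()] or [fit_hybrid_encoding()].
#' @return A numeric matrix (samples x markers) with dimnames.
#' @export
apply_encoding <- function(g, table) {
  codes <- unclass(g)
  if (anyNA(codes)) stop("genotypes contain missing values", call. = FALSE)
  idx <- match(colnames(codes), table$marker_id)
  if (anyNA(idx)) {
    stop("marker(s) absent from encoding table: ",
         paste(colnames(codes)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  E <- cbind(table$e0, table$e1, table$e2)[idx, , drop = FALSE]
  n <- nrow(codes)
  out <- matrix(NA_real_, n, ncol(codes), dimnames = dimnames(codes))
  for (cd in 0:2) {
    sel <- codes == cd
    out[sel] <- matrix(E[, cd + 1L], n, ncol(codes), byrow = TRUE)[sel]
  }
  out
}

#' Apply a pairwise grid encoding
#'
#' Produces one real-valued feature per marker pair, named `"i:j"`, whose
#' value for a sample is the grid cell indexed by the sample's two genotype
#' codes.
#'
#' @param g A [geno_matrix()] with no missing entries.
#' @param table A pair-encoding tibble from [fit_pair_encoding()].
#' @return A numeric matrix (samples x pairs); zero columns if `table` has
#'   no rows.
#' @export
apply_pair_encoding <- function(g, table) {
  codes <- unclass(g)
  if (anyNA(codes)) stop("genotypes contain missing values", call. = FALSE)
  np <- nrow(table)
  feat <- if (np > 0L) paste0(table$marker_i, ":", table$marker_j)
          else character(0)
  out <- matrix(NA_real_, nrow(codes), np,
                dimnames = list(rownames(codes), feat))
  if (np == 0L) return(out)
  missing_m <- setdiff(c(table$marker_i, table$marker_j), colnames(codes))
  if (length(missing_m)) {
    stop("pair marker(s) absent from genotype matrix: ",
         paste(unique(missing_m), collapse = ", "), call. = FALSE)
  }
  grid_cols <- paste0("e", rep(0:2, each = 3), rep(0:2, times = 3))
  G <- as.matrix(table[, grid_cols])
  ci <- match(table$marker_i, colnames(codes))
  cj <- match(table$marker_j, colnames(codes))
  for (k in seq_len(np)) {
    cell <- codes[, ci[k]] * 3L + codes[, cj[k]] + 1L  # index into e00..e22
    out[, k] <- G[k, cell]
  }
  out
}

#' Product (multiplicative) epistasis features
#'
#' The classical interaction term: feature `"i:j"` is the elementwise
#' product of the two encoded single-marker features. Used as the baseline
#' epistasis design under fixed encodings, where it is sensitive to the
#' scheme — codes (1, 1) give 1 under \{0, 1, 2\} but 0 under \{-1, 0, 1\},
#' and (0, 1) and (0, 2) both collapse to 0 under \{0, 1, 2\}.
#'
#' @param X An encoded matrix (samples x features) as returned by
#'   [apply_encoding()].
#' @param pairs Data frame with columns `marker_i`, `marker_j` referencing
#'   feature ids of `X`.
#' @return A numeric matrix (samples x pairs) with `"i:j"` feature names.
#' @export
product_features <- function(X, pairs) {
  pr <- canonical_pairs(pairs, colnames(X))
  out <- X[, pr$marker_i, drop = FALSE] * X[, pr$marker_j, drop = FALSE]
  colnames(out) <- paste0(pr$marker_i, ":", pr$marker_j)
  out
}

#' Serialize encoding tables
#'
#' Writes a single-marker encoding table (marker id, e0, e1, e2, fallback)
#' or a pair table (pair ids plus the nine grid cells) to TSV for audit.
#'
#' @param table An encoding or pair-encoding tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_encoding_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}
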