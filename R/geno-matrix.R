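#' Construct a genotype matrix
#'
#' The central genotype container: an `n` samples by `m` markers integer
#' matrix of biallelic genotype codes. Code 0 and 2 are the two homozygotes,
#' 1 the heterozygote; by convention code 2 counts the alternate (VCF ALT)
#' allele twice, so it is an ALT-dosage, not necessarily a minor-allele
#' dosage. Missing genotypes are stored as `NA` — an out-of-band sentinel, so
#' -1 stays available as a legal *encoding* value under the \{-1, 0, 1\}
#' scheme.
#'
#' @param codes Integer (or coercible) matrix with entries in \{0, 1, 2, NA\}.
#' @param sample_ids Character vector of unique sample ids (rows). Defaults
#'   to `rownames(codes)`.
#' @param marker_ids Character vector of unique marker ids (columns).
#'   Defaults to `colnames(codes)`.
#' @return An object of class `geno_matrix`: an integer matrix with sample
#'   ids as rownames and marker ids as colnames.
#' @examples
#' g <- geno_matrix(rbind(c(0, 1), c(2, NA)),
#'                  sample_ids = c("s1", "s2"),
#'                  marker_ids = c("m1", "m2"))
#' n_samples(g)
#' @export
geno_matrix <- function(codes, sample_ids = rownames(codes),
                        marker_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(codes)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- paste0("marker", seq_len(ncol(codes)))
  }
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(codes)) {
    stop("`sample_ids` length (", length(sample_ids),
         ") does not match row count (", nrow(codes), ")", call. = FALSE)
  }
  if (length(marker_ids) != ncol(codes)) {
    stop("`marker_ids` length (", length(marker_ids),
         ") does not match column count (", ncol(codes), ")", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         codes[bad][1], " at sample '", sample_ids[idx[1]],
         "', marker '", marker_ids[idx[2]], "'", call. = FALSE)
  }
  dimnames(codes) <- list(sample_ids, marker_ids)
  structure(codes, class = c("geno_matrix", "matrix", "array"))
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) nrow(x)

#' @rdname geno_matrix
#' @export
n_markers <- function(x) ncol(x)

#' @rdname geno_matrix
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname geno_matrix
#' @export
marker_ids <- function(x) colnames(x)

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x), " samples x ", ncol(x), " markers; ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

# subsetting keeps the class and dimnames (drop is forced off)
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  structure(out, class = c("geno_matrix", "matrix", "array"))
}

#' Construct a phenotype table
#'
#' Phenotypes travel as a tibble with one row per sample: `sample_id` and a
#' finite real `value` (trait units are arbitrary).
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param values Numeric trait values, one per sample, all finite.
#' @return A tibble with columns `sample_id`, `value`.
#' @export
pheno_tbl <- function(sample_ids, values) {
  sample_ids <- as.character(sample_ids)
  values <- as.numeric(values)
  if (length(sample_ids) != length(values)) {
    stop("one trait value per sample id required", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in phenotype: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("trait values must be finite", call. = FALSE)
  }
  tibble::tibble(sample_id = sample_ids, value = values)
}

check_pheno <- function(pheno) {
  if (!is.data.frame(pheno) || !all(c("sample_id", "value") %in% names(pheno))) {
    stop("phenotype must be a data frame with columns `sample_id` and `value`",
         call. = FALSE)
  }
  pheno_tbl(pheno$sample_id, pheno$value)
}

#' Align a genotype matrix and a phenotype table
#'
#' Restricts both objects to the intersection of their sample ids and puts
#' them in a single canonical order (the genotype matrix's sample order).
#' Marker order is untouched.
#'
#' @param g A [geno_matrix()].
#' @param pheno A phenotype tibble (`sample_id`, `value`).
#' @return A list with elements `geno` and `pheno`, sharing one sample order.
#' @export
align_genotypes <- function(g, pheno) {
  pheno <- check_pheno(pheno)
  if (nrow(g) == 0L || nrow(pheno) == 0L) {
    stop("both genotype matrix and phenotype table must be nonempty",
         call. = FALSE)
  }
  keep <- intersect(rownames(g), pheno$sample_id)
  if (length(keep) == 0L) {
    stop("no shared sample ids between genotypes (", nrow(g),
         " ids) and phenotypes (", nrow(pheno), " ids)", call. = FALSE)
  }
  keep <- rownames(g)[rownames(g) %in% keep]  # canonical = genotype order
  g2 <- g[keep, ]
  p2 <- pheno[match(keep, pheno$sample_id), ]
  list(geno = g2, pheno = p2)
}

#' Filter markers on missingness, minor allele frequency and heterozygosity
#'
#' A marker is kept iff its missing fraction is at most `max_missing_rate`,
#' its minor allele frequency is at least `min_maf`, and its heterozygote
#' fraction is at most `max_heterozygosity` (all comparisons
#' boundary-inclusive for "keep"). MAF is `min(p, 1 - p)` with
#' `p = (2 * n2 + n1) / (2 * n_nonmissing)`, the alternate-allele frequency.
#' The defaults reproduce a common SNP-array cleaning rule (MAF >= 0.001,
#' missingness <= 10%); heterozygosity filtering is off by default.
#'
#' @param g A [geno_matrix()].
#' @param max_missing_rate Maximum tolerated missing fraction in `[0, 1]`.
#' @param min_maf Minimum minor allele frequency in `[0, 0.5]`.
#' @param max_heterozygosity Maximum heterozygote fraction in `[0, 1]`.
#' @return A list: `geno` (the filtered matrix) and `dropped`, a tibble with
#'   one row per dropped marker (`marker_id`, `reason`), the reason being the
#'   first failing rule in the order missing, maf, het.
#' @export
filter_markers <- function(g, max_missing_rate = 0.1, min_maf = 0.001,
                           max_heterozygosity = 1) {
  if (nrow(g) == 0L || ncol(g) == 0L) stop("genotype matrix is empty", call. = FALSE)
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            max_heterozygosity >= 0, max_heterozygosity <= 1)
  codes <- unclass(g)
  n <- nrow(codes)
  n_miss <- colSums(is.na(codes))
  n_obs <- n - n_miss
  n_het <- colSums(codes == 1L, na.rm = TRUE)
  n_alt_hom <- colSums(codes == 2L, na.rm = TRUE)
  p <- ifelse(n_obs > 0, (2 * n_alt_hom + n_het) / (2 * n_obs), 0)
  maf <- pmin(p, 1 - p)
  miss_rate <- n_miss / n
  het_rate <- ifelse(n_obs > 0, n_het / n_obs, 0)

  fail_miss <- miss_rate > max_missing_rate
  fail_maf <- maf < min_maf
  fail_het <- het_rate > max_heterozygosity
  reason <- rep(NA_character_, ncol(codes))
  reason[fail_het] <- "het"
  reason[fail_maf] <- "maf"
  reason[fail_miss] <- "missing"  # last write wins => priority missing > maf > het
  dropped <- tibble::tibble(marker_id = colnames(codes)[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  kept <- g[, is.na(reason)]
  if (ncol(kept) == 0L) {
    warning("all markers were dropped by the filter", call. = FALSE)
  }
  list(geno = kept, dropped = dropped)
}

#' Impute missing genotypes by the per-marker mode
#'
#' Each missing entry is replaced by the most frequent non-missing code of
#' its marker, with ties broken toward the smaller code. Modal (not mean)
#' imputation keeps codes in \{0, 1, 2\}, which the data-driven encoders
#' require.
#'
#' @param g A [geno_matrix()]; every marker must have at least one observed
#'   genotype.
#' @return A `geno_matrix` with no missing entries; observed entries are
#'   untouched.
#' @export
impute_missing <- function(g) {
  codes <- unclass(g)
  if (!anyNA(codes)) return(g)
  counts <- vapply(0:2, function(cd) colSums(codes == cd, na.rm = TRUE),
                   numeric(ncol(codes)))
  if (ncol(codes) == 1L) counts <- matrix(counts, nrow = 1L)
  all_missing <- rowSums(counts) == 0
  if (any(all_missing)) {
    stop("marker(s) entirely missing: ",
         paste(colnames(codes)[all_missing], collapse = ", "), call. = FALSE)
  }
  modal <- max.col(counts, ties.method = "first") - 1L  # first = smaller code
  for (j in seq_len(ncol(codes))) {
    miss <- is.na(codes[, j])
    if (any(miss)) codes[miss, j] <- modal[j]
  }
  geno_matrix(codes, rownames(codes), colnames(codes))
}
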