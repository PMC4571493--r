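#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file with a GT field into a [geno_matrix()] of ALT
#' dosages: `0/0` → 0, `0/1` or `1/0` → 1, `1/1` → 2; phased separators
#' (`|`) are treated like `/`; `./.` and half-calls (`0/.`) become missing.
#' Sites with more than one ALT allele are skipped with a warning. Marker
#' id is the ID column, falling back to `CHROM:POS` (1-based POS, as
#' printed) when ID is `.`.
#'
#' @param path Path to an (optionally bgzipped) VCF file.
#' @return A [geno_matrix()] (samples x markers).
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop("failed to parse VCF '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    stop("VCF '", path, "' has no sample genotype (GT) data", call. = FALSE)
  }
  ids <- fix[, "ID"]
  fallback <- is.na(ids) | ids == "."
  ids[fallback] <- paste0(fix[fallback, "CHROM"], ":", fix[fallback, "POS"])
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  ids <- ids[keep]
  if (anyDuplicated(ids)) {
    stop("duplicate marker ids in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  codes <- apply(gt, c(1, 2), gt_to_code)
  if (length(codes) == 0L) stop("VCF '", path, "' has no usable sites",
                                call. = FALSE)
  geno_matrix(t(codes), sample_ids = colnames(gt), marker_ids = ids)
}

gt_to_code <- function(gt) {
  if (is.na(gt) || gt == ".") return(NA_integer_)
  alleles <- strsplit(chartr("|", "/", gt), "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2L) {
    stop("malformed GT '", gt, "' (expected diploid call)", call. = FALSE)
  }
  if (any(alleles == ".")) return(NA_integer_)  # half-calls are missing
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a) || any(a > 1L) || any(a < 0L)) {
    stop("GT '", gt, "' is not biallelic diploid", call. = FALSE)
  }
  sum(a)
}

#' Read genotypes from a sample-by-marker TSV
#'
#' Expects marker ids in the first (header) row, sample ids in the first
#' column, and cells in \{0, 1, 2, NA\} (`NA` case-insensitive, or empty).
#'
#' @param path Path to a TSV file.
#' @return A [geno_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = character())
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("genotype TSV '", path, "' has no data section", call. = FALSE)
  }
  samples <- df[[1]]
  codes <- parse_code_cells(df[-1], samples, path)
  geno_matrix(codes, sample_ids = samples, marker_ids = names(df)[-1])
}

parse_code_cells <- function(df, samples, path) {
  codes <- matrix(NA_integer_, nrow(df), ncol(df))
  for (j in seq_along(df)) {
    cell <- trimws(df[[j]])
    is_na <- toupper(cell) == "NA" | cell == ""
    val <- suppressWarnings(as.integer(cell))
    bad <- !is_na & (is.na(val) | !(val %in% 0:2) |
                       cell != as.character(val))
    if (any(bad)) {
      i <- which(bad)[1]
      stop("invalid genotype cell '", df[[j]][i], "' at row '", samples[i],
           "', column '", names(df)[j], "' in '", path, "'", call. = FALSE)
    }
    val[is_na] <- NA_integer_
    codes[, j] <- val
  }
  codes
}

#' Write genotypes as a sample-by-marker TSV
#'
#' The inverse of [read_genotype_tsv()]: missing entries are written as
#' `NA`.
#'
#' @param g A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  codes <- unclass(g)
  lines <- c(paste(c("sample_id", colnames(codes)), collapse = "\t"),
             vapply(seq_len(nrow(codes)), function(i) {
               paste(c(rownames(codes)[i],
                       ifelse(is.na(codes[i, ]), "NA", codes[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a PLINK .raw file
#'
#' Whitespace-separated PLINK "recode A" dialect: header columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per marker with
#' additively coded genotypes in \{0, 1, 2, NA\}. The sample id is `IID`;
#' the PHENOTYPE column is ignored (phenotypes come from
#' [read_phenotype()]).
#'
#' @param path Path to a .raw file.
#' @return A [geno_matrix()].
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  mandatory <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (nrow(df) == 0L) stop(".raw file '", path, "' has no sample rows",
                           call. = FALSE)
  if (!identical(names(df)[seq_along(mandatory)], mandatory)) {
    stop(".raw header must start with: ", paste(mandatory, collapse = " "),
         call. = FALSE)
  }
  if (ncol(df) <= length(mandatory)) {
    stop(".raw file '", path, "' has no marker columns", call. = FALSE)
  }
  samples <- df$IID
  geno_cols <- df[-seq_along(mandatory)]
  codes <- parse_code_cells(geno_cols, samples, path)
  geno_matrix(codes, sample_ids = samples, marker_ids = names(geno_cols))
}

#' Read a phenotype table
#'
#' Two-column TSV (sample id, numeric trait) with an optional header row
#' (detected by a non-numeric second field). Any non-numeric trait value
#' after the header is an error, as is a duplicated sample id.
#'
#' @param path Path to a TSV file.
#' @return A phenotype tibble (`sample_id`, `value`).
#' @export
read_phenotype <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("phenotype file '", path, "' is empty",
                                call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("phenotype file '", path, "' must have two tab-separated columns",
         call. = FALSE)
  }
  first_val <- suppressWarnings(as.numeric(parts[[1]][2]))
  if (is.na(first_val)) parts <- parts[-1]  # header row
  if (length(parts) == 0L) stop("phenotype file '", path,
                                "' has no data rows", call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 1)
  raw <- vapply(parts, `[`, character(1), 2)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    stop("non-numeric trait value '", raw[which(is.na(vals))[1]],
         "' for sample '", ids[which(is.na(vals))[1]], "' in '", path, "'",
         call. = FALSE)
  }
  pheno_tbl(ids, vals)
}

#' Write a phenotype table
#'
#' @param pheno Phenotype tibble (`sample_id`, `value`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  pheno <- check_pheno(pheno)
  writeLines(c("sample_id\tvalue",
               paste0(pheno$sample_id, "\t", format_full(pheno$value))),
             path)
  invisible(path)
}

#' Read and write encoded (real-valued) design matrices
#'
#' TSV with sample ids in the first column and feature ids in the header.
#' Values are written with 17 significant digits, so a write/read
#' round-trip reproduces the matrix bit-faithfully.
#'
#' @param X A numeric matrix (samples x features) with dimnames, e.g. from
#'   [apply_encoding()].
#' @param path File path.
#' @return `write_encoded()` returns `path` invisibly; `read_encoded()`
#'   returns the numeric matrix.
#' @export
write_encoded <- function(X, path) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) {
    stop("encoded matrix is empty", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("encoded matrix has non-finite values",
                               call. = FALSE)
  lines <- c(paste(c("sample_id", colnames(X)), collapse = "\t"),
             vapply(seq_len(nrow(X)), function(i) {
               paste(c(rownames(X)[i], format_full(X[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("encoded matrix file '", path, "' has no data", call. = FALSE)
  }
  # as.numeric (strtod) is correctly rounded, preserving the 17-digit
  # serialization bit-for-bit
  X <- vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, 1L, dimnames = list(NULL, names(df)[-1]))
  rownames(X) <- df[[1]]
  X
}
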