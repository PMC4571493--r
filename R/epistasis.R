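#' Mutual information between a categorical feature and a trait
#'
#' Plug-in mutual information in bits between a categorical feature and the
#' trait discretized into `bins` equal-frequency (quantile) bins over the
#' given samples: \eqn{I = \sum_{x,b} p(x,b) \log_2 p(x,b)/(p(x)p(b))},
#' with \eqn{0 \log 0 \equiv 0}. Heavily tied traits collapse bins (the
#' quantile breaks are deduplicated); a constant trait occupies a single
#' bin, so its MI is exactly 0.
#'
#' @param x Categorical feature values, one per sample (any atomic type;
#'   values are compared as categories).
#' @param y Numeric trait values, same length.
#' @param bins Number of quantile bins for the trait (default 10).
#' @return Mutual information in bits (nonnegative scalar).
#' @export
mi_bits <- function(x, y, bins = 10) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  b <- trait_bins(y, bins)
  tab <- table(x, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  pb <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, pb)[nz]))
}

# equal-frequency bin index of the trait; constant trait -> single bin
trait_bins <- function(y, bins) {
  brks <- unique(stats::quantile(y, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE, type = 7))
  if (length(brks) < 2L) return(rep(1L, length(y)))
  as.integer(cut(y, breaks = brks, include.lowest = TRUE))
}

# fixed per-marker scheme used inside encoding combos: "012" identity,
# "210" reverses the codes
combo_schemes <- list(E1 = c("012", "012"), E2 = c("012", "210"),
                      E3 = c("210", "012"), E4 = c("210", "210"))

scheme_values <- function(codes, scheme) {
  if (scheme == "012") codes else 2L - codes
}

#' Rank all marker pairs by mutual information to the trait
#'
#' For every unordered marker pair (i, j), forms the multiplicative
#' interaction term under one of four fixed encoding combinations —
#' `E1` = (\{0,1,2\}, \{0,1,2\}), `E2` = (\{0,1,2\}, \{2,1,0\}),
#' `E3` = (\{2,1,0\}, \{0,1,2\}), `E4` = (\{2,1,0\}, \{2,1,0\}) — and ranks
#' the pairs by the mutual information between the product values (treated
#' as categories) and the discretized trait. Products deliberately merge
#' genotype cells (e.g. under \{0,1,2\} the pairs (0,1) and (0,2) both give
#' 0), which is exactly why the chosen combination changes the ranking.
#'
#' @param g A [geno_matrix()] with at least 2 markers and no missing
#'   entries.
#' @param pheno Phenotype tibble aligned (or alignable) to `g`.
#' @param combo `"E1"`, `"E2"`, `"E3"` or `"E4"`.
#' @param bins Quantile bins for the trait (see [mi_bits()]).
#' @param max_pairs Safety cap on the number of pairs enumerated; raise it
#'   explicitly for large marker panels.
#' @return A tibble (`marker_i`, `marker_j`, `mi_bits`, `rank`) sorted by
#'   descending MI, ties broken by (i, j) marker order; pairs are stored
#'   with i before j in the matrix's column order.
#' @export
rank_pairs <- function(g, pheno, combo = c("E1", "E2", "E3", "E4"),
                       bins = 10, max_pairs = 1e6) {
  combo <- match.arg(combo)
  inp <- encoding_inputs(g, pheno)
  codes <- inp$codes
  m <- ncol(codes)
  if (m < 2L) stop("need at least 2 markers to rank pairs", call. = FALSE)
  n_pairs <- m * (m - 1) / 2
  if (n_pairs > max_pairs) {
    stop(n_pairs, " pairs exceed max_pairs = ", max_pairs,
         "; raise `max_pairs` to override", call. = FALSE)
  }
  sch <- combo_schemes[[combo]]
  b <- trait_bins(inp$y, bins)
  v1 <- scheme_values(codes, sch[1])
  v2 <- scheme_values(codes, sch[2])
  ii <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  jj <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
  mi <- numeric(length(ii))
  for (k in seq_along(ii)) {
    mi[k] <- mi_from_bins(v1[, ii[k]] * v2[, jj[k]], b)
  }
  out <- tibble::tibble(marker_i = colnames(codes)[ii],
                        marker_j = colnames(codes)[jj],
                        mi_bits = mi)
  out <- out[order(-out$mi_bits, ii, jj), ]
  out$rank <- seq_len(nrow(out))
  out
}

# mi_bits with the trait already binned (avoids re-binning per pair)
mi_from_bins <- function(x, b) {
  tab <- table(x, b)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  pb <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, pb)[nz]))
}

#' Keep the top k pairs of a ranked list
#'
#' @param ranked A ranked pair tibble from [rank_pairs()].
#' @param k Number of pairs to keep (clamped to the list length).
#' @return The first `min(k, nrow)` rows.
#' @export
top_pairs <- function(ranked, k) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  utils::head(ranked, k)
}

#' Average-overlap similarity of two ranked pair lists
#'
#' Rank correlation for lists that need not contain the same elements: the
#' mean, over prefix depths `1..depth`, of the fraction of pairs shared by
#' the two top-k prefixes,
#' \eqn{\frac{1}{K}\sum_{k=1}^{K} |a_{1:k} \cap b_{1:k}| / k}.
#' Pairs are compared as unordered marker-id sets. Identical lists score 1,
#' disjoint lists 0; the measure is symmetric in its arguments.
#'
#' @param a,b Ranked pair tibbles (columns `marker_i`, `marker_j`), each
#'   with at least `depth` rows.
#' @param depth Maximum prefix depth `K`; defaults to the shorter list
#'   length.
#' @return A scalar in `[0, 1]`.
#' @export
average_overlap <- function(a, b, depth = NULL) {
  key <- function(d) {
    paste(pmin(d$marker_i, d$marker_j), pmax(d$marker_i, d$marker_j),
          sep = "\r")
  }
  ka <- key(a)
  kb <- key(b)
  if (is.null(depth)) depth <- min(length(ka), length(kb))
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (length(ka) < depth || length(kb) < depth) {
    stop("both lists must have at least `depth` = ", depth, " entries",
         call. = FALSE)
  }
  acc <- 0
  for (k in seq_len(depth)) {
    acc <- acc + length(intersect(ka[seq_len(k)], kb[seq_len(k)])) / k
  }
  acc / depth
}

#' Average-overlap matrix across the four encoding combinations
#'
#' Ranks all pairs under each of E1–E4 and reports the pairwise
#' average-overlap similarity of the four ranked lists.
#'
#' @inheritParams rank_pairs
#' @param depth Prefix depth for [average_overlap()]; default full length.
#' @return A list: `rankings` (named list of ranked tibbles) and `overlap`,
#'   a 4x4 numeric matrix.
#' @export
combo_overlap_matrix <- function(g, pheno, bins = 10, depth = NULL,
                                 max_pairs = 1e6) {
  combos <- names(combo_schemes)
  rankings <- lapply(combos, function(cm) {
    rank_pairs(g, pheno, combo = cm, bins = bins, max_pairs = max_pairs)
  })
  names(rankings) <- combos
  ov <- matrix(NA_real_, 4, 4, dimnames = list(combos, combos))
  for (i in seq_along(combos)) for (j in seq_along(combos)) {
    ov[i, j] <- average_overlap(rankings[[i]], rankings[[j]], depth = depth)
  }
  list(rankings = rankings, overlap = ov)
}
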