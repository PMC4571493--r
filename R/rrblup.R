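#' Ridge regression with a fixed shrinkage parameter
#'
#' Solves the penalized least squares problem
#' \deqn{\min_{\beta_0,\beta} \sum_l (y_l - \beta_0 - x_l^\top\beta)^2 +
#'   \lambda \|\beta\|^2}
#' with an unpenalized intercept, handled by centering `y` and the columns
#' of `X` and back-transforming. For `p <= n` the primal normal equations
#' are used; for `p > n` the dual identity
#' \eqn{\beta = X^\top (XX^\top + \lambda I)^{-1} y} keeps the cost at
#' `min(n, p)^3` and never materializes the p x p cross-product.
#'
#' @param X Numeric design matrix (samples x features) with finite entries
#'   and unique column names; zero columns are allowed (intercept-only fit).
#' @param y Numeric response, or a phenotype tibble (`sample_id`, `value`)
#'   whose ids then must match `rownames(X)`.
#' @param lambda Positive shrinkage parameter.
#' @return A `ridge_blup` object: list with `intercept`, named
#'   `coefficients`, `lambda`, `sigma2_beta`, `sigma2_e`, `reml_loglik`
#'   (NA unless REML-fit), `feature_ids`, `method`.
#' @seealso [ridge_reml()] for the variance-component (rrBLUP) choice of
#'   `lambda`, [predict.ridge_blup()], [tidy.ridge_blup()].
#' @export
ridge_fixed <- function(X, y, lambda) {
  xy <- ridge_inputs(X, y)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  fit <- ridge_core(xy$X, xy$y, lambda)
  new_ridge_blup(fit, lambda, sigma2_beta = NA_real_, sigma2_e = NA_real_,
                 reml_loglik = NA_real_, method = "fixed")
}

ridge_inputs <- function(X, y) {
  if (is.data.frame(y)) {
    y <- check_pheno(y)
    if (is.null(rownames(X)) || !setequal(rownames(X), y$sample_id)) {
      stop("rownames(X) must match the phenotype sample ids", call. = FALSE)
    }
    y <- y$value[match(rownames(X), y$sample_id)]
  }
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("X and y are not aligned", call. = FALSE)
  if (ncol(X) > 0 && any(!is.finite(X))) {
    stop("X contains non-finite values", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("y contains non-finite values", call. = FALSE)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  list(X = X, y = as.numeric(y))
}

# centered ridge solve; returns intercept + coefficients
ridge_core <- function(X, y, lambda) {
  n <- nrow(X)
  p <- ncol(X)
  ybar <- mean(y)
  if (p == 0L) {
    return(list(intercept = ybar,
                coefficients = stats::setNames(numeric(0), character(0))))
  }
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  if (p <= n) {
    beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  } else {
    K <- tcrossprod(Xc)
    alpha <- solve(K + diag(lambda, n), yc)
    beta <- crossprod(Xc, alpha)
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  list(intercept = ybar - sum(xbar * beta), coefficients = beta)
}

new_ridge_blup <- function(fit, lambda, sigma2_beta, sigma2_e, reml_loglik,
                           method) {
  structure(list(intercept = fit$intercept,
                 coefficients = fit$coefficients,
                 lambda = lambda,
                 sigma2_beta = sigma2_beta,
                 sigma2_e = sigma2_e,
                 reml_loglik = reml_loglik,
                 feature_ids = names(fit$coefficients),
                 method = method),
            class = "ridge_blup")
}

#' Ridge-regression BLUP with REML-estimated shrinkage
#'
#' Fits the mixed model \eqn{y = 1\beta_0 + Xu + e} with iid marker effects
#' \eqn{u \sim N(0, \sigma^2_\beta I)} and residuals
#' \eqn{e \sim N(0, \sigma^2_e I)}, and returns the ridge (BLUP) solution at
#' \eqn{\lambda = \sigma^2_e / \sigma^2_\beta} — the variance-component
#' ratio that makes penalized ridge equal the best linear unbiased
#' predictor. The restricted likelihood is profiled down to a 1-D function
#' of \eqn{\lambda} via the spectral decomposition of the marker kernel
#' \eqn{XX^\top} projected onto contrasts orthogonal to the intercept, then
#' maximized on a log grid refined by [stats::optimize()]
#' (bounds `1e-6`–`1e6`, tolerance `1e-8` in log-lambda); hitting a bound
#' raises a warning, not an error.
#'
#' @inheritParams ridge_fixed
#' @return A `ridge_blup` object (see [ridge_fixed()]) with REML
#'   `sigma2_beta`, `sigma2_e`, `reml_loglik` filled in and
#'   `lambda = sigma2_e / sigma2_beta` exactly.
#' @export
ridge_reml <- function(X, y) {
  xy <- ridge_inputs(X, y)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (n < 3L) stop("REML needs at least 3 samples", call. = FALSE)
  if (ncol(X) == 0L || all(apply(X, 2L, function(col) diff(range(col)) == 0))) {
    stop("X has no nonconstant feature; lambda is unidentifiable", call. = FALSE)
  }

  # contrasts orthogonal to the intercept: T is n x (n-1), orthonormal
  Tm <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  K <- tcrossprod(Xc)
  M <- crossprod(Tm, K %*% Tm)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  phi <- pmax(eg$values, 0)
  eta <- drop(crossprod(eg$vectors, crossprod(Tm, y)))
  nr <- n - 1L

  # profile restricted log-likelihood in log10(lambda); on the contrast
  # eigenbasis eta_i ~ N(0, sigma2_beta * (phi_i + lambda)), and with
  # sigma2_beta profiled out (sigma2_beta_hat = S/nr, S = sum eta^2/(phi+lam))
  # the likelihood reduces, up to constants, to the expression below
  ll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    d <- phi + lam
    -0.5 * (sum(log(d)) + nr * log(sum(eta^2 / d)))
  }

  lo <- -6; hi <- 6
  grid <- seq(lo, hi, length.out = 121)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(ll, interval = bracket, maximum = TRUE, tol = 1e-8)
  log10_lam <- opt$maximum
  if (log10_lam <= lo + 1e-6 || log10_lam >= hi - 1e-6) {
    warning("REML lambda estimate at optimization bound (lambda = ",
            signif(10^log10_lam, 3), ")", call. = FALSE)
  }
  lam <- 10^log10_lam
  sigma2_beta <- sum(eta^2 / (phi + lam)) / nr
  sigma2_e <- lam * sigma2_beta

  fit <- ridge_core(X, y, lam)
  new_ridge_blup(fit, lam, sigma2_beta = sigma2_beta, sigma2_e = sigma2_e,
                 reml_loglik = reml_restricted_loglik(phi, eta, lam, nr),
                 method = "reml")
}

# full restricted log-likelihood (with constants) at the optimum
reml_restricted_loglik <- function(phi, eta, lam, nr) {
  sigma2_beta <- sum(eta^2 / (phi + lam)) / nr
  d <- sigma2_beta * (phi + lam)
  -0.5 * (nr * log(2 * pi) + sum(log(d)) + sum(eta^2 / d))
}

#' Predict from a fitted ridge-BLUP model
#'
#' @param object A `ridge_blup` fit.
#' @param X_new Encoded matrix whose column names are exactly the model's
#'   feature ids (any order; columns are realigned).
#' @param ... Unused.
#' @return Numeric vector of predictions, named by `rownames(X_new)`.
#' @export
predict.ridge_blup <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (length(object$feature_ids) == 0L) {
    return(stats::setNames(rep(object$intercept, nrow(X_new)),
                           rownames(X_new)))
  }
  if (is.null(colnames(X_new)) ||
      !setequal(colnames(X_new), object$feature_ids)) {
    missing_f <- setdiff(object$feature_ids, colnames(X_new))
    extra_f <- setdiff(colnames(X_new), object$feature_ids)
    stop("feature mismatch; missing: [",
         paste(utils::head(missing_f, 5), collapse = ", "),
         "], extra: [", paste(utils::head(extra_f, 5), collapse = ", "), "]",
         call. = FALSE)
  }
  X_new <- X_new[, object$feature_ids, drop = FALSE]
  drop(object$intercept + X_new %*% object$coefficients)
}

#' @export
print.ridge_blup <- function(x, ...) {
  cat("<ridge_blup> ", length(x$coefficients), " features; lambda = ",
      signif(x$lambda, 4), " (", x$method, ")\n", sep = "")
  if (x$method == "reml") {
    cat("  sigma2_beta = ", signif(x$sigma2_beta, 4),
        ", sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a ridge-BLUP fit
#'
#' `tidy()` returns one row per model term (intercept first); `glance()`
#' returns a one-row model summary.
#'
#' @param x,object A `ridge_blup` fit.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ridge_blup <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_ids),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.ridge_blup
#' @exportS3Method generics::glance
glance.ridge_blup <- function(x, ...) {
  tibble::tibble(n_features = length(x$coefficients),
                 lambda = x$lambda,
                 sigma2_beta = x$sigma2_beta,
                 sigma2_e = x$sigma2_e,
                 reml_loglik = x$reml_loglik,
                 method = x$method)
}

#' Serialize a fitted model to TSV
#'
#' Writes a header block (intercept, lambda, variance components) as
#' commented lines followed by a (feature_id, coefficient) table.
#'
#' @param model A `ridge_blup` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  hdr <- c(paste0("# intercept\t", format_full(model$intercept)),
           paste0("# lambda\t", format_full(model$lambda)),
           paste0("# sigma2_beta\t", format_full(model$sigma2_beta)),
           paste0("# sigma2_e\t", format_full(model$sigma2_e)))
  writeLines(c(hdr, "feature_id\tcoefficient",
               paste0(model$feature_ids, "\t",
                      format_full(unname(model$coefficients)))),
             path)
  invisible(path)
}

format_full <- function(x) sprintf("%.17g", x)
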