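#' Principal-axis factor analysis of a correlation matrix
#'
#' Single-pass principal-axis factoring: the diagonal of the correlation
#' matrix is replaced by squared-multiple-correlation (SMC) communality
#' priors and the loadings are the leading eigenvectors of the reduced
#' matrix scaled by the square roots of their eigenvalues. No communality
#' iteration is performed. A `method = "pca"` flag extracts principal
#' components instead (unit diagonal retained).
#'
#' When the correlation matrix is numerically singular (more variables than
#' observations, or duplicated variables) the SMC computation falls back to
#' a small ridge; in that regime the priors saturate near 1 and extraction
#' approaches principal components.
#'
#' If fewer than `n_factors` eigenvalues are positive, the trailing loading
#' columns are zero and a warning is issued.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param n_factors number of factors to extract.
#' @param method `"pa"` (principal axis, default) or `"pca"`.
#' @return An object of class `factor_solution`: list with `loadings`
#'   (variables x factors), `communalities`, `variance_explained` (sum of
#'   squared loadings per factor, in eigenvalue units of one standardized
#'   variable), `n_input`, and `method`. `scores` is `NULL` until computed.
#' @export
principal_factor_analysis <- function(corr, n_factors, method = c("pa", "pca")) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (p != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    stop("corr must be a symmetric matrix")
  }
  if (max(abs(diag(corr) - 1)) > 1e-8) {
    stop("corr must have a unit diagonal")
  }
  if (n_factors < 1 || n_factors > p) {
    stop("n_factors must be between 1 and the number of variables")
  }
  red <- corr
  if (method == "pa") {
    inv <- solve_maybe_ridge(corr, diag(p))
    smc <- 1 - 1 / diag(inv)
    smc <- pmin(pmax(smc, 0), 1)
    diag(red) <- smc
  }
  ee <- eigen((red + t(red)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(ee$values[1]))
  k_pos <- sum(ee$values > tol)
  if (k_pos < n_factors) {
    warning(sprintf("only %d factor(s) with positive eigenvalues (requested %d); remaining loading columns are zero",
                    k_pos, n_factors))
  }
  L <- matrix(0, p, n_factors)
  m <- min(k_pos, n_factors)
  if (m > 0) {
    L[, seq_len(m)] <- ee$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(ee$values[seq_len(m)]), m)
  }
  rownames(L) <- rownames(corr)
  colnames(L) <- paste0("F", seq_len(n_factors))
  structure(list(loadings = L,
                 communalities = rowSums(L^2),
                 variance_explained = colSums(L^2),
                 scores = NULL,
                 n_input = p,
                 method = method),
            class = "factor_solution")
}

#' Varimax rotation with deterministic column signs
#'
#' Orthogonally rotates a loading matrix to maximize the (Kaiser-normalized)
#' varimax criterion, then fixes each column's sign so its largest-|loading|
#' entry is positive. Row communalities are preserved by the rotation.
#' Columns with (numerically) zero sum of squares, and rows with zero
#' communality, are excluded from the rotation search and passed through.
#'
#' @param loadings variables x factors matrix; a single column is returned
#'   unchanged.
#' @param normalize apply Kaiser row normalization during the search.
#' @param eps convergence tolerance on the varimax criterion.
#' @return the rotated loading matrix.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, eps = 1e-8) {
  loadings <- as.matrix(loadings)
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  if (ncol(loadings) < 2) return(fix_column_signs(loadings))
  nz_col <- colSums(loadings^2) > 1e-12
  L <- loadings
  if (sum(nz_col) >= 2) {
    sub <- loadings[, nz_col, drop = FALSE]
    nz_row <- rowSums(sub^2) > 1e-12
    rot <- stats::varimax(sub[nz_row, , drop = FALSE],
                          normalize = normalize, eps = eps)
    L[, nz_col] <- sub %*% rot$rotmat
  }
  fix_column_signs(L)
}

fix_column_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (length(i) && L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

# Rotate a factor_solution's loadings in place, updating variance explained
# (communalities are rotation invariant).
rotate_solution <- function(solution, normalize = TRUE, eps = 1e-8) {
  solution$loadings <- varimax_rotate(solution$loadings, normalize, eps)
  solution$variance_explained <- colSums(solution$loadings^2)
  solution
}

# Raw varimax criterion (sum over factors of the variance of squared
# loadings), optionally Kaiser-normalized. Used by tests as a grid-search
# oracle and by property checks.
varimax_criterion <- function(L, normalize = TRUE) {
  L <- as.matrix(L)
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h < 1e-12] <- 1
    L <- L / h
  }
  p <- nrow(L)
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2)) * p
}

#' Estimate factor scores by the regression method
#'
#' Computes regression-method (Thurstone) factor score estimates
#' `Z %*% solve(R) %*% L` for standardized data `Z`, loadings `L` and the
#' input correlation matrix `R`. A singular correlation matrix triggers a
#' ridge fallback (reported via [message()]).
#'
#' @param data concepts x variables matrix; standardized internally.
#' @param loadings variables x factors loading matrix.
#' @param corr correlation matrix of the variables; computed from `data`
#'   when omitted.
#' @param standardize if `TRUE`, z-score the estimated score columns
#'   (regression scores always have mean 0; their variance is below 1).
#' @return concepts x factors score matrix (columns mean 0).
#' @export
factor_scores <- function(data, loadings, corr = NULL, standardize = FALSE) {
  Z <- zscore(data)
  if (is.null(corr)) corr <- stats::cor(data)
  B <- solve_maybe_ridge(corr, as.matrix(loadings), quiet = FALSE)
  S <- Z %*% B
  S <- sweep(S, 2, colMeans(S), "-")
  if (standardize) S <- zscore(S)
  colnames(S) <- colnames(loadings)
  S
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("factor_solution (%s): %d variables x %d factors\n",
              x$method, nrow(x$loadings), ncol(x$loadings)))
  cat("variance explained (SS loadings):",
      paste(sprintf("%.3f", x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}
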