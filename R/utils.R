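# Internal helpers shared across modules.

LOBE_NAMES <- c("frontal", "parietal", "temporal-fusiform", "occipital")

# Deterministic seed splitting: every stochastic unit (participant, rater,
# permutation) draws from a seed derived by hashing the master seed with the
# unit's indices, so unit i is reproducible independently of how many other
# units exist. All arithmetic stays below 2^53, hence identical across
# platforms; the result stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  s <- as.double(as.integer(seed)) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + (as.double(k) + 1) * 104729) %% 2147483647
  }
  as.integer(s)
}

# Column-standardize; constant columns are left centred at zero.
zscore <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < tol] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

# Solve R %*% x = b with a small ridge fallback when R is numerically
# singular (e.g. more input columns than observations).
solve_maybe_ridge <- function(R, b, ridge = 1e-6, quiet = TRUE) {
  rc <- tryCatch(rcond(R), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-10) {
    return(solve(R, b))
  }
  lam <- ridge * mean(diag(R))
  if (!quiet) message(sprintf(
    "near-singular correlation matrix; applying ridge regularization %.3e", lam))
  solve(R + diag(lam, nrow(R)), b)
}

# Pearson correlation between matching columns of two matrices, returned as
# a vector (NA where either column has zero variance).
colwise_pearson <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A), "-")
  Bc <- sweep(B, 2, colMeans(B), "-")
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  out <- colSums(Ac * Bc) / den
  out[!is.finite(den) | den == 0] <- NA_real_
  out
}

# Mean over a subset of presentations of a concepts x presentations x voxels
# array, returning a concepts x voxels matrix.
presentation_mean <- function(psc, presentations = seq_len(dim(psc)[2])) {
  C <- dim(psc)[1]
  M <- matrix(0, C, dim(psc)[3])
  for (p in presentations) M <- M + matrix(psc[, p, ], nrow = C)
  M / length(presentations)
}

# Greedy maximum-|r| bipartite matching on a correlation matrix. Returns a
# data.frame with one row per matched (row, col) pair, strongest first.
greedy_match <- function(C) {
  C <- as.matrix(C)
  A <- abs(C)
  rows <- integer(0); cols <- integer(0); rs <- numeric(0)
  while (any(is.finite(A)) && length(rows) < min(nrow(A), ncol(A))) {
    idx <- which(A == max(A, na.rm = TRUE), arr.ind = TRUE)
    # deterministic tie-break: smallest row index, then column index
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    rows <- c(rows, idx[1]); cols <- c(cols, idx[2])
    rs <- c(rs, C[idx[1], idx[2]])
    A[idx[1], ] <- -Inf
    A[, idx[2]] <- -Inf
  }
  data.frame(row = rows, col = cols, r = rs)
}
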