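#' Individual-level factor analysis, one per lobe
#'
#' Averages the dataset over presentations, selects the `n_per_lobe` most
#' stable voxels within each of the four lobes, computes the correlation
#' matrix of those voxels' concept-activation profiles, and factor-analyses
#' it (principal-axis extraction, varimax rotation, regression-method
#' scores). Running the analysis separately per lobe prevents any single
#' region (typically occipital) from dominating the stable-voxel pool.
#'
#' @param dataset an `activation_dataset`.
#' @param n_per_lobe stable voxels selected per lobe (default 120).
#' @param n_factors factors extracted per lobe (default 10); reduced with a
#'   warning when a lobe has too few usable voxels.
#' @param stability optional precomputed [voxel_stability()] scores; by
#'   default computed from all presentations of `dataset`.
#' @return An object of class `individual_fa`: list with one element per
#'   lobe, each containing `solution` (a `factor_solution` whose `scores`
#'   are z-scored concepts x factors) and `voxels` (the input voxel
#'   indices, in loading-row order).
#' @export
individual_level_fa <- function(dataset, n_per_lobe = 120, n_factors = 10,
                                stability = NULL) {
  geometry <- dataset$geometry
  if (is.null(stability)) stability <- voxel_stability(dataset$psc)
  M <- presentation_mean(dataset$psc)
  sel_by_lobe <- select_stable_voxels(stability, n_per_lobe, lobe = geometry$lobe)
  out <- list()
  for (lb in LOBE_NAMES) {
    sel <- sel_by_lobe[[lb]]
    X <- M[, sel, drop = FALSE]
    nf <- n_factors
    if (length(sel) <= nf) {
      nf <- max(1L, length(sel) - 1L)
      warning(sprintf("lobe '%s': only %d usable voxels; extracting %d factor(s)",
                      lb, length(sel), nf))
    }
    R <- stats::cor(X)
    sol <- suppressWarnings(principal_factor_analysis(R, nf))
    sol <- rotate_solution(sol)
    sol$scores <- factor_scores(X, sol$loadings, R, standardize = TRUE)
    rownames(sol$scores) <- dataset$concept_labels
    out[[lb]] <- list(solution = sol, voxels = sel, lobe = lb)
  }
  structure(list(lobes = out, participant_id = dataset$participant_id),
            class = "individual_fa")
}

# Concepts x columns matrix of all individual-level factor scores from a
# list of individual_fa objects, with informative column names.
stack_individual_scores <- function(solutions) {
  cols <- list()
  nm <- character(0)
  for (s in seq_along(solutions)) {
    fa <- solutions[[s]]
    for (lb in names(fa$lobes)) {
      sc <- fa$lobes[[lb]]$solution$scores
      cols[[length(cols) + 1]] <- sc
      nm <- c(nm, paste0("p", s, ".", lb, ".", colnames(sc)))
    }
  }
  n_rows <- vapply(cols, nrow, 1L)
  if (length(unique(n_rows)) != 1) stop("inconsistent concept sets across inputs")
  S <- do.call(cbind, cols)
  colnames(S) <- nm
  S
}

#' Group-level factor analysis over individual factor scores
#'
#' Pools the individual-level factor scores of the selected participants
#' into a concepts x columns matrix (one column per participant, lobe and
#' factor), factor-analyses its correlation matrix, and retains the factors
#' whose sum of squared loadings (eigenvalue, in units of one standardized
#' input column) is at least `variance_threshold`. The default threshold of
#' 1 is the Kaiser rule: a retained factor must explain at least as much
#' variance as a single input column. Retained factors are varimax-rotated
#' and scored by the regression method.
#'
#' @param solutions list of `individual_fa` objects (or a ready-made
#'   concepts x columns score matrix).
#' @param variance_threshold retention threshold in eigenvalue units.
#' @param max_factors cap on the number of factors considered (default 20).
#' @return a `factor_solution` over the concepts, with `loadings` (input
#'   columns x retained factors), z-scored `scores`, `variance_explained`
#'   and `input_names`. With no factor above threshold an empty solution
#'   (zero factor columns) is returned with a warning.
#' @export
group_level_fa <- function(solutions, variance_threshold = 1, max_factors = 20) {
  S <- if (is.matrix(solutions)) solutions else stack_individual_scores(solutions)
  keep <- apply(S, 2, stats::sd) > 1e-10
  S <- S[, keep, drop = FALSE]
  if (ncol(S) == 0) stop("no non-constant input columns")
  R <- stats::cor(S)
  n_extract <- min(max_factors, ncol(S), nrow(S) - 1)
  sol <- suppressWarnings(principal_factor_analysis(R, n_extract))
  retained <- which(sol$variance_explained >= variance_threshold)
  if (!length(retained)) {
    warning("no factor reaches the variance threshold; returning an empty solution")
    empty <- matrix(0, ncol(S), 0, dimnames = list(colnames(S), NULL))
    return(structure(list(loadings = empty,
                          communalities = rep(0, ncol(S)),
                          variance_explained = numeric(0),
                          scores = matrix(0, nrow(S), 0),
                          n_input = ncol(S),
                          input_names = colnames(S),
                          method = "pa"),
                     class = "factor_solution"))
  }
  L <- sol$loadings[, retained, drop = FALSE]
  L <- varimax_rotate(L)
  colnames(L) <- paste0("G", seq_len(ncol(L)))
  scores <- factor_scores(S, L, R, standardize = TRUE)
  rownames(scores) <- rownames(S)
  structure(list(loadings = L,
                 communalities = rowSums(L^2),
                 variance_explained = colSums(L^2),
                 scores = scores,
                 n_input = ncol(S),
                 input_names = colnames(S),
                 method = "pa"),
            class = "factor_solution")
}

#' Secondary factor analysis of unassigned cluster columns
#'
#' Applies the group-level factor analysis to the residual score columns
#' that were not associated with any retained (interpretable) factor, to
#' recover dimensions missed at the first level. With no input an empty
#' solution is returned (not an error); a single column is passed through
#' as a one-factor solution.
#'
#' @param residual_scores concepts x columns matrix of residual factor
#'   scores (possibly zero columns).
#' @inheritParams group_level_fa
#' @return a `factor_solution` (possibly empty).
#' @export
secondary_fa <- function(residual_scores, variance_threshold = 1,
                         max_factors = 20) {
  residual_scores <- as.matrix(residual_scores)
  if (ncol(residual_scores) == 0) {
    empty <- matrix(0, 0, 0)
    return(structure(list(loadings = empty, communalities = numeric(0),
                          variance_explained = numeric(0),
                          scores = matrix(0, nrow(residual_scores), 0),
                          n_input = 0, input_names = character(0),
                          method = "pa"),
                     class = "factor_solution"))
  }
  if (ncol(residual_scores) == 1) {
    sc <- zscore(residual_scores)
    colnames(sc) <- "G1"
    return(structure(list(loadings = matrix(1, 1, 1,
                                            dimnames = list(colnames(residual_scores), "G1")),
                          communalities = 1,
                          variance_explained = 1,
                          scores = sc,
                          n_input = 1,
                          input_names = colnames(residual_scores),
                          method = "pa"),
                     class = "factor_solution"))
  }
  group_level_fa(residual_scores, variance_threshold, max_factors)
}

#' Voxel loadings on group-level factors
#'
#' Structure loadings of individual voxels on a set of factor scores: the
#' Pearson correlation between each voxel's presentation-averaged concept
#' activation profile and each factor's concept scores. These loadings are
#' what [assign_voxels_to_factors()] thresholds to map factors back onto
#' the brain.
#'
#' @param dataset an `activation_dataset`, or a concepts x voxels matrix of
#'   presentation-averaged activation.
#' @param scores concepts x factors matrix of factor scores.
#' @return voxels x factors matrix of correlations (0 where the voxel
#'   profile has zero variance).
#' @export
voxel_factor_loadings <- function(dataset, scores) {
  M <- if (inherits(dataset, "activation_dataset")) {
    presentation_mean(dataset$psc)
  } else {
    as.matrix(dataset)
  }
  L <- suppressWarnings(stats::cor(M, scores))
  L[!is.finite(L)] <- 0
  L
}

#' Assign voxels to factors by thresholded absolute loading
#'
#' Each voxel is uniquely assigned to the factor on which it has its
#' highest absolute loading, provided that loading exceeds the threshold;
#' otherwise it stays unassigned. An empty mapping is allowed.
#'
#' @param loadings voxels x factors matrix of finite loadings.
#' @param threshold absolute-loading threshold (default 0.4).
#' @return integer vector (length = number of voxels) of factor column
#'   indices, `NA` where unassigned.
#' @export
assign_voxels_to_factors <- function(loadings, threshold = 0.4) {
  loadings <- as.matrix(loadings)
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  a <- apply(loadings, 1, function(r) {
    j <- which.max(abs(r))
    if (abs(r[j]) > threshold) j else NA_integer_
  })
  as.integer(a)
}

#' Align factor solutions across participants
#'
#' Greedy maximum-|r| bipartite matching of factor score columns: every
#' solution is matched against the first one, reporting the correlation and
#' sign of each matched pair and listing unmatched factors.
#'
#' @param solutions list of `factor_solution` objects or score matrices
#'   over a shared concept set.
#' @return list with one data.frame per input (columns `ref_factor`,
#'   `factor`, `r`, `sign`); attribute `unmatched` lists per input the
#'   factor columns left unmatched.
#' @export
align_factors <- function(solutions) {
  get_scores <- function(s) if (inherits(s, "factor_solution")) s$scores else as.matrix(s)
  ref <- get_scores(solutions[[1]])
  out <- vector("list", length(solutions))
  unmatched <- vector("list", length(solutions))
  for (i in seq_along(solutions)) {
    sc <- get_scores(solutions[[i]])
    if (nrow(sc) != nrow(ref)) stop("solutions must share the concept set")
    C <- stats::cor(ref, sc)
    m <- greedy_match(C)
    out[[i]] <- data.frame(ref_factor = m$row, factor = m$col,
                           r = m$r, sign = sign(m$r))
    unmatched[[i]] <- setdiff(seq_len(ncol(sc)), m$col)
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Correlate factor scores with behavioral ratings
#'
#' Pearson correlation (with a two-sided t-test p-value) between each
#' factor's concept scores and the corresponding mean expert ratings,
#' either over all concepts or over the `extremes_k` concepts at the two
#' ends of the factor-score distribution (k/2 highest and k/2 lowest).
#'
#' @param scores concepts x dimensions factor scores.
#' @param ratings concepts x dimensions `ratings_matrix` (columns matched
#'   by name when both are named, otherwise by position).
#' @param subset `"all"` or `"extremes"`.
#' @param extremes_k number of extreme concepts used in `"extremes"` mode.
#' @return data.frame with columns `dimension`, `n`, `r`, `p`.
#' @export
correlate_scores_with_ratings <- function(scores, ratings,
                                          subset = c("all", "extremes"),
                                          extremes_k = 10) {
  subset <- match.arg(subset)
  scores <- as.matrix(scores)
  ratings <- as.matrix(ratings)
  if (nrow(scores) != nrow(ratings)) stop("concept sets must match")
  if (!is.null(colnames(scores)) && !is.null(colnames(ratings))) {
    common <- intersect(colnames(scores), colnames(ratings))
    if (!length(common)) stop("no shared dimension names")
    scores <- scores[, common, drop = FALSE]
    ratings <- ratings[, common, drop = FALSE]
  } else if (ncol(scores) != ncol(ratings)) {
    stop("unnamed inputs must have the same number of dimensions")
  }
  res <- lapply(seq_len(ncol(scores)), function(d) {
    x <- scores[, d]; y <- ratings[, d]
    if (subset == "extremes") {
      k2 <- floor(extremes_k / 2)
      ord <- order(x)
      pick <- c(ord[seq_len(k2)], ord[seq(length(ord) - k2 + 1, length(ord))])
      x <- x[pick]; y <- y[pick]
    }
    if (stats::sd(y) == 0) {
      stop(sprintf("undefined correlation: ratings for dimension %s are constant",
                   colnames(scores)[d] %||% d))
    }
    ct <- stats::cor.test(x, y)
    data.frame(dimension = colnames(scores)[d] %||% as.character(d),
               n = length(x), r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match recovered factors against planted ground-truth dimensions
#'
#' Greedy maximum-|r| matching between a factor solution's concept scores
#' and the generator's planted dimension scores. Used to validate planted
#' structure recovery on synthetic cohorts.
#'
#' @param solution a `factor_solution` (or score matrix).
#' @param gt a `ground_truth`.
#' @return data.frame with one row per planted dimension: `dimension`,
#'   `factor` (matched column index, `NA` if none left), `r`.
#' @export
match_factors_to_truth <- function(solution, gt) {
  sc <- if (inherits(solution, "factor_solution")) solution$scores else as.matrix(solution)
  truth <- gt$concept_scores
  if (ncol(sc) == 0) {
    return(data.frame(dimension = colnames(truth),
                      factor = NA_integer_, r = NA_real_))
  }
  C <- stats::cor(truth, sc)
  m <- greedy_match(C)
  out <- data.frame(dimension = colnames(truth), factor = NA_integer_,
                    r = NA_real_)
  out$factor[m$row] <- m$col
  out$r[m$row] <- m$r
  out
}

#' Write factor scores as TSV
#' @param scores concepts x factors matrix with concept rownames.
#' @param path output path.
#' @export
write_factor_scores_tsv <- function(scores, path) {
  df <- data.frame(concept = rownames(scores) %||% seq_len(nrow(scores)),
                   as.data.frame(unclass(scores)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
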