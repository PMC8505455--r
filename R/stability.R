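#' Score voxel stability across stimulus presentations
#'
#' A voxel's stability is the mean, over all pairs of presentations, of the
#' Pearson correlation between the voxel's two concept-activation profiles
#' (its vector of activation levels across all concepts). High stability
#' means the voxel's semantic tuning curve replicates across presentations.
#'
#' Voxels whose profile is constant within any presentation have an
#' undefined correlation; they are assigned the sentinel `-Inf` ("never
#' selected") and their count is reported via [message()]. Stability is
#' invariant to any positive affine rescaling applied per presentation.
#'
#' @param psc concepts x presentations x voxels array (>= 2 concepts and
#'   >= 2 presentations), typically the training presentations of the
#'   current cross-validation fold only.
#' @return numeric vector of per-voxel scores in [-1, 1] (or `-Inf`), with
#'   attribute `presentations` recording how many presentations were used.
#' @export
voxel_stability <- function(psc) {
  d <- dim(psc)
  if (length(d) != 3) stop("psc must be a concepts x presentations x voxels array")
  C <- d[1]; P <- d[2]; V <- d[3]
  if (C < 2) stop("need at least 2 concepts")
  if (P < 2) stop("need at least 2 presentations")
  pairs <- utils::combn(P, 2)
  acc <- matrix(NA_real_, V, ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    A <- matrix(psc[, pairs[1, q], ], nrow = C)
    B <- matrix(psc[, pairs[2, q], ], nrow = C)
    acc[, q] <- colwise_pearson(A, B)
  }
  score <- rowMeans(acc)
  bad <- apply(acc, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    score[bad] <- -Inf
    message(sprintf("voxel_stability: %d voxel(s) with zero variance marked unselectable",
                    sum(bad)))
  }
  attr(score, "presentations") <- P
  score
}

#' Select the most stable voxels, whole-brain or per region
#'
#' Returns the `n` highest-scoring voxels. Ties at the cutoff are broken by
#' ascending voxel index; voxels with non-finite scores (the zero-variance
#' sentinel) are never selected. If a region holds fewer than `n` scoreable
#' voxels, all of them are returned with a warning.
#'
#' @param scores per-voxel stability (or consistency) scores.
#' @param n number of voxels to select per region.
#' @param lobe optional character vector of per-voxel region labels; when
#'   supplied, selection is performed separately within each region and a
#'   named list of index vectors is returned. When `NULL` (whole-brain
#'   mode, used by the classifiers) a single integer vector is returned.
#' @return integer vector of selected voxel indices (ascending), or a named
#'   list of such vectors in per-region mode.
#' @export
select_stable_voxels <- function(scores, n, lobe = NULL) {
  if (n < 1) stop("n must be at least 1")
  pick <- function(idx, region) {
    sc <- scores[idx]
    ok <- is.finite(sc)
    if (!any(ok)) stop(sprintf("region '%s' has no scoreable voxels", region))
    idx <- idx[ok]; sc <- sc[ok]
    ord <- idx[order(-sc, idx)]
    if (length(ord) < n) {
      warning(sprintf("region '%s': only %d scoreable voxels available (requested %d)",
                      region, length(ord), n))
      return(sort(ord))
    }
    sort(ord[seq_len(n)])
  }
  if (is.null(lobe)) {
    return(pick(seq_along(scores), "whole-brain"))
  }
  if (length(lobe) != length(scores)) stop("lobe must label every voxel")
  regions <- unique(lobe)
  out <- lapply(regions, function(r) pick(which(lobe == r), r))
  names(out) <- regions
  out
}

# Top-n voxels by score among a candidate set, returned in descending score
# order (ties by ascending index). Internal: used where ordering matters.
top_by_score <- function(scores, candidates, n) {
  sc <- scores[candidates]
  ok <- is.finite(sc)
  cand <- candidates[ok]
  sc <- sc[ok]
  ord <- cand[order(-sc, cand)]
  ord[seq_len(min(n, length(ord)))]
}

#' Cross-participant consistency of voxel activation profiles
#'
#' For each voxel, the mean over all participant pairs of the Pearson
#' correlation between the two participants' concept-activation profiles at
#' that voxel. Used to pick classifier features with a consistent semantic
#' profile across the training participants; top-`n` selection reuses
#' [select_stable_voxels()] in whole-brain mode.
#'
#' @param mean_activations list (one per participant) of concepts x voxels
#'   matrices of presentation-averaged activation, on a shared geometry.
#' @return numeric vector of per-voxel consistency scores (sentinel `-Inf`
#'   where any participant's profile has zero variance).
#' @export
cross_participant_consistency <- function(mean_activations) {
  if (!is.list(mean_activations) || length(mean_activations) < 2) {
    stop("need mean activation matrices from at least 2 participants")
  }
  dims <- lapply(mean_activations, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1) {
    stop("participants must share concept and voxel dimensions")
  }
  n <- length(mean_activations)
  pairs <- utils::combn(n, 2)
  V <- ncol(mean_activations[[1]])
  acc <- matrix(NA_real_, V, ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    acc[, q] <- colwise_pearson(mean_activations[[pairs[1, q]]],
                                mean_activations[[pairs[2, q]]])
  }
  score <- rowMeans(acc)
  bad <- apply(acc, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    score[bad] <- -Inf
    message(sprintf("cross_participant_consistency: %d voxel(s) with zero variance marked unselectable",
                    sum(bad)))
  }
  score
}

#' Export a stability table as TSV
#'
#' Writes one row per voxel with grid indices, mm coordinates, lobe label
#' and score.
#'
#' @param scores per-voxel scores.
#' @param geometry the matching `brain_geometry`.
#' @param path output file path.
#' @export
write_stability_tsv <- function(scores, geometry, path) {
  mm <- voxel_mm(geometry)
  df <- data.frame(voxel = seq_along(scores),
                   x = mm[, 1], y = mm[, 2], z = mm[, 3],
                   lobe = geometry$lobe, score = as.numeric(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
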