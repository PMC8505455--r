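#' Cluster-level mean activation features
#'
#' For each factor cluster, takes a cuboid of voxels around the cluster
#' centroid, ranks the cuboid's voxels by stability, and averages the
#' activation (presentation mean) of the top `n_voxels`. Clusters with
#' fewer than `n_voxels` member voxels are excluded from the feature set
#' and reported, since their mean would be computed over a different
#' support.
#'
#' @param dataset an `activation_dataset` (or a concepts x voxels matrix,
#'   in which case `geometry` and `stability` must be supplied).
#' @param cluster_map a `cluster_map` or cluster set (list of clusters).
#' @param n_voxels voxels averaged per cluster (default 5).
#' @param cuboid_radius half-width of the cuboid around the centroid in
#'   voxels (default 1, i.e. a 3 x 3 x 3 neighborhood).
#' @param stability per-voxel stability used for the ranking; defaults to
#'   [voxel_stability()] over all presentations of `dataset`.
#' @param geometry required when `dataset` is a plain matrix.
#' @return concepts x clusters feature matrix with attributes `excluded`
#'   (data.frame of excluded clusters) and `chosen_voxels` (list of voxel
#'   indices per retained cluster).
#' @export
cluster_mean_activation <- function(dataset, cluster_map, n_voxels = 5,
                                    cuboid_radius = 1, stability = NULL,
                                    geometry = NULL) {
  clusters <- if (inherits(cluster_map, "cluster_map")) cluster_map$clusters else cluster_map
  if (!length(clusters)) stop("cluster_map contains no clusters")
  if (inherits(dataset, "activation_dataset")) {
    geometry <- dataset$geometry
    if (is.null(stability)) stability <- voxel_stability(dataset$psc)
    M <- presentation_mean(dataset$psc)
  } else {
    if (is.null(geometry) || is.null(stability)) {
      stop("matrix input requires geometry and stability")
    }
    M <- as.matrix(dataset)
  }
  feats <- list()
  chosen <- list()
  excluded <- data.frame(cluster = integer(0), factor = integer(0),
                         size = integer(0))
  short <- 0L
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (cl$size < n_voxels) {
      excluded <- rbind(excluded, data.frame(cluster = ci, factor = cl$factor,
                                             size = cl$size))
      next
    }
    centre <- mm_to_ijk(geometry, cl$centroid)
    lo <- pmax(centre - cuboid_radius, 1)
    hi <- pmin(centre + cuboid_radius, geometry$grid_shape)
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    pool <- ijk_to_index(geometry, box)
    top <- top_by_score(stability, pool, n_voxels)
    if (length(top) < n_voxels) short <- short + 1L
    feats[[length(feats) + 1]] <- rowMeans(M[, top, drop = FALSE])
    chosen[[length(chosen) + 1]] <- top
  }
  if (!length(feats)) stop("all clusters were excluded (size < n_voxels)")
  if (short > 0) {
    warning(sprintf("%d cluster cuboid(s) held fewer than %d scoreable voxels; used all available",
                    short, n_voxels))
  }
  out <- do.call(cbind, feats)
  colnames(out) <- paste0("cluster", seq_len(ncol(out)))
  attr(out, "excluded") <- excluded
  attr(out, "chosen_voxels") <- chosen
  out
}

#' Fit the ratings-to-activation forward regression
#'
#' Ordinary least squares, fitted independently per cluster with an
#' intercept: the mean activation of each factor cluster is modelled as a
#' linear function of the concept's mean ratings on the semantic
#' dimensions.
#'
#' @param ratings (n-1) x d matrix of mean ratings (one column per
#'   semantic dimension); rater means, not z-scored.
#' @param activations (n-1) x clusters matrix of cluster mean activations.
#' @return An object of class `predictive_model`: list with `weights`
#'   ((d+1) x clusters, intercept first) and `dimensions`.
#' @export
fit_ratings_regression <- function(ratings, activations) {
  ratings <- as.matrix(ratings)
  activations <- as.matrix(activations)
  n <- nrow(ratings)
  d <- ncol(ratings)
  if (nrow(activations) != n) stop("ratings and activations must align")
  if (n <= d + 1) stop("need more concepts than predictors plus intercept")
  X <- cbind(`(Intercept)` = 1, ratings)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # identify the offending predictor for the error message
    culprit <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design; degenerate predictor column(s): ",
         paste(culprit, collapse = ", "))
  }
  W <- qr.coef(qx, activations)
  structure(list(weights = W,
                 dimensions = colnames(ratings)),
            class = "predictive_model")
}

#' Predict a concept's cluster activation pattern from its ratings
#'
#' @param model a `predictive_model`.
#' @param rating_row named (or correctly ordered) vector of the concept's
#'   mean ratings on the model's dimensions.
#' @return numeric vector of predicted activation, one value per cluster.
#' @export
predict_concept_pattern <- function(model, rating_row) {
  d <- nrow(model$weights) - 1
  if (!is.null(names(rating_row)) && !is.null(model$dimensions)) {
    miss <- setdiff(model$dimensions, names(rating_row))
    if (length(miss)) stop("missing rating dimension(s): ",
                           paste(miss, collapse = ", "))
    rating_row <- rating_row[model$dimensions]
  } else if (length(rating_row) != d) {
    stop(sprintf("rating_row must supply %d dimensions", d))
  }
  as.numeric(c(1, rating_row) %*% model$weights)
}

#' Leave-one-concept-out evaluation of the forward model
#'
#' For each held-out concept the regression is refitted on the remaining
#' concepts, the model predicts the activation patterns of *all* concepts
#' from their ratings, and two measures are taken: (1) goodness of fit,
#' R^2 = squared Pearson correlation between the held-out concept's
#' predicted and observed cluster vectors; (2) discriminability, the
#' normalized rank (ascending correlation distance
#' `1 - r(observed, predicted)`) of the correct concept among all
#' predicted patterns.
#'
#' @param ratings n x d matrix of mean ratings.
#' @param activations n x clusters matrix of observed cluster activations.
#' @param details keep the per-fold weight matrices (for leakage audits).
#' @return list with `per_concept_r2`, `mean_r2`, `rank_accuracy` (a
#'   `rank_accuracy` object), `predictions` (n x clusters, each row from
#'   its own fold), and optionally `fold_weights`.
#' @export
loo_evaluate <- function(ratings, activations, details = FALSE) {
  ratings <- as.matrix(ratings)
  activations <- as.matrix(activations)
  n <- nrow(ratings)
  if (n < 7) stop("need at least 7 concepts for leave-one-out evaluation")
  labels <- rownames(ratings) %||% as.character(seq_len(n))
  r2 <- rep(NA_real_, n)
  preds <- matrix(NA_real_, n, ncol(activations))
  scores <- matrix(NA_real_, n, n, dimnames = list(NULL, labels))
  fw <- if (details) vector("list", n) else NULL
  dropped <- 0L
  for (cc in seq_len(n)) {
    model <- fit_ratings_regression(ratings[-cc, , drop = FALSE],
                                    activations[-cc, , drop = FALSE])
    if (details) fw[[cc]] <- model$weights
    pred_all <- cbind(1, ratings) %*% model$weights
    obs <- activations[cc, ]
    preds[cc, ] <- pred_all[cc, ]
    if (stats::sd(obs) == 0) {
      dropped <- dropped + 1L
      next
    }
    r2[cc] <- stats::cor(obs, pred_all[cc, ])^2
    scores[cc, ] <- as.numeric(stats::cor(obs, t(pred_all)))
  }
  if (dropped > 0) {
    warning(sprintf("%d concept(s) with zero-variance observed patterns excluded from R^2",
                    dropped))
  }
  ok <- !is.na(scores[, 1])
  ra <- rank_accuracy(scores[ok, , drop = FALSE], labels[ok])
  list(per_concept_r2 = stats::setNames(r2, labels),
       mean_r2 = mean(r2, na.rm = TRUE),
       rank_accuracy = ra,
       predictions = preds,
       fold_weights = fw)
}
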