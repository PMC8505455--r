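#' Union of replicated factor clusters across two groups
#'
#' Pools the per-participant cluster maps of two groups, groups clusters
#' into sites (same factor identity, centroids within
#' `max_centroid_dist_vox` voxels), keeps the sites replicated in at least
#' `min_participants` participants of their source group, and merges
#' overlapping sites across groups. The factor identities of the two
#' groups' maps must be expressed in a common labelling (align the group
#' factor solutions first, e.g. with [align_factors()]).
#'
#' @param cluster_maps_a,cluster_maps_b lists of `cluster_map`s, one per
#'   participant of each group, on a shared geometry.
#' @param min_participants replication filter (default 4).
#' @param max_centroid_dist_vox maximum per-axis centroid distance, in
#'   voxels, for two clusters to count as the same site (default 1).
#' @return list of clusters (`factor`, `voxels` union, `size`, `centroid`
#'   mm, `lobe`, `support_a`, `support_b` participant counts); errors if
#'   the union is empty.
#' @export
union_factor_clusters <- function(cluster_maps_a, cluster_maps_b,
                                  min_participants = 4,
                                  max_centroid_dist_vox = 1) {
  geometry <- cluster_maps_a[[1]]$geometry
  vs <- geometry$voxel_size_mm

  collect_sites <- function(maps) {
    sites <- list()
    for (i in seq_along(maps)) {
      for (cl in maps[[i]]$clusters) {
        cv <- (cl$centroid - geometry$origin) / vs + 1
        best <- 0L; bestd <- Inf
        for (s in seq_along(sites)) {
          if (!identical(sites[[s]]$factor, cl$factor)) next
          d <- max(abs(sites[[s]]$centroid_vox - cv))
          if (d <= max_centroid_dist_vox && d < bestd) { best <- s; bestd <- d }
        }
        if (best == 0L) {
          sites[[length(sites) + 1]] <- list(factor = cl$factor,
                                             centroid_vox = cv,
                                             centroids = list(cv),
                                             participants = i,
                                             voxels = cl$voxels)
        } else {
          st <- sites[[best]]
          st$centroids <- c(st$centroids, list(cv))
          st$centroid_vox <- Reduce(`+`, st$centroids) / length(st$centroids)
          st$participants <- union(st$participants, i)
          st$voxels <- union(st$voxels, cl$voxels)
          sites[[best]] <- st
        }
      }
    }
    Filter(function(s) length(s$participants) >= min_participants, sites)
  }

  sa <- collect_sites(cluster_maps_a)
  sb <- collect_sites(cluster_maps_b)

  merged <- list()
  used_b <- logical(length(sb))
  for (s in sa) {
    hit <- 0L; bestd <- Inf
    for (t in seq_along(sb)) {
      if (used_b[t] || !identical(sb[[t]]$factor, s$factor)) next
      d <- max(abs(sb[[t]]$centroid_vox - s$centroid_vox))
      if (d <= max_centroid_dist_vox && d < bestd) { hit <- t; bestd <- d }
    }
    vox <- if (hit > 0L) union(s$voxels, sb[[hit]]$voxels) else s$voxels
    if (hit > 0L) used_b[hit] <- TRUE
    merged[[length(merged) + 1]] <-
      list(factor = s$factor, voxels = sort(vox), size = length(vox),
           support_a = length(s$participants),
           support_b = if (hit > 0L) length(sb[[hit]]$participants) else 0L)
  }
  for (t in seq_along(sb)) {
    if (used_b[t]) next
    merged[[length(merged) + 1]] <-
      list(factor = sb[[t]]$factor, voxels = sort(sb[[t]]$voxels),
           size = length(sb[[t]]$voxels),
           support_a = 0L, support_b = length(sb[[t]]$participants))
  }
  if (!length(merged)) stop("empty cluster union after the replication filter")
  for (m in seq_along(merged)) {
    mm <- voxel_mm(geometry, merged[[m]]$voxels)
    merged[[m]]$centroid <- colMeans(mm)
    merged[[m]]$lobe <- names(which.max(table(geometry$lobe[merged[[m]]$voxels])))
  }
  ord <- order(vapply(merged, function(m) as.numeric(m$factor), 1),
               vapply(merged, function(m) min(m$voxels), 1))
  merged[ord]
}

#' Build per-participant group-comparison features
#'
#' For each participant, restricts the data to the shared concept subset,
#' scores voxel stability on those concepts across presentations, and for
#' each cluster averages the presentation-mean activation of the cluster's
#' top-`n_voxels` most stable voxels. Clusters with fewer voxels use all
#' of them (with one warning).
#'
#' @param datasets list of `activation_dataset`s (both groups).
#' @param cluster_set cluster list from [union_factor_clusters()] (or a
#'   `cluster_map`).
#' @param shared_concepts concept labels or indices common to both groups.
#' @param n_voxels voxels averaged per cluster (default 6).
#' @return An object of class `group_feature_table`: list with `features`
#'   (per participant, concepts x clusters matrix), `group` (label per
#'   participant), `concepts`.
#' @export
build_group_features <- function(datasets, cluster_set, shared_concepts,
                                 n_voxels = 6) {
  clusters <- if (inherits(cluster_set, "cluster_map")) cluster_set$clusters else cluster_set
  if (!length(shared_concepts)) stop("shared_concepts must be nonempty")
  feats <- lapply(datasets, function(d) {
    idx <- if (is.character(shared_concepts)) {
      match(shared_concepts, d$concept_labels)
    } else {
      as.integer(shared_concepts)
    }
    if (any(is.na(idx))) stop("shared concept absent from a participant's dataset")
    sub <- d$psc[idx, , , drop = FALSE]
    stab <- voxel_stability(sub)
    M <- presentation_mean(sub)
    f <- vapply(clusters, function(cl) {
      top <- top_by_score(stab, cl$voxels, n_voxels)
      rowMeans(M[, top, drop = FALSE])
    }, numeric(length(idx)))
    colnames(f) <- paste0("cluster", seq_along(clusters))
    f
  })
  n_small <- sum(vapply(clusters, function(cl) cl$size < n_voxels, TRUE))
  if (n_small > 0) {
    warning(sprintf("%d cluster(s) smaller than %d voxels; all member voxels used",
                    n_small, n_voxels))
  }
  structure(list(features = feats,
                 group = vapply(datasets, function(d) d$group, ""),
                 concepts = if (is.character(shared_concepts)) shared_concepts
                            else datasets[[1]]$concept_labels[shared_concepts]),
            class = "group_feature_table")
}

#' Leave-one-participant-out group membership classification
#'
#' Flattens each participant's (concept subset x clusters) feature block
#' into one vector, then cross-validates a pooled-variance Gaussian naive
#' Bayes group classifier leaving one participant out per fold.
#'
#' @param feature_table a `group_feature_table`.
#' @param concept_subset indices (into the table's concepts) to use;
#'   default all.
#' @return list with `accuracy`, `predictions`, `truth`, `n_folds`.
#' @export
classify_group_membership <- function(feature_table, concept_subset = NULL) {
  n <- length(feature_table$features)
  if (is.null(concept_subset)) {
    concept_subset <- seq_along(feature_table$concepts)
  }
  if (!length(concept_subset)) stop("concept_subset must be nonempty")
  y <- factor(feature_table$group)
  if (any(table(y) < 2)) stop("need at least 2 participants per group")
  X <- t(vapply(feature_table$features, function(m) {
    as.numeric(m[concept_subset, , drop = FALSE])
  }, numeric(length(concept_subset) * ncol(feature_table$features[[1]]))))
  preds <- character(n)
  for (i in seq_len(n)) {
    model <- train_gnb(X[-i, , drop = FALSE], y[-i])
    preds[i] <- predict(model, X[i, , drop = FALSE], type = "class")
  }
  list(accuracy = mean(preds == as.character(y)),
       predictions = preds,
       truth = as.character(y),
       n_folds = n)
}

#' Reiterative stepwise selection of discriminating concepts
#'
#' Beam-style greedy search for the concept subset whose features best
#' discriminate the groups: iteration 1 evaluates every single concept and
#' keeps the best (with ties); iteration k extends every surviving
#' (k-1)-set with each remaining concept and keeps the extensions whose
#' accuracy is at least as high as the best accuracy of the previous
#' iteration. The search stops when every extension strictly decreases
#' accuracy (or concepts are exhausted). Ties in the final set are broken
#' by the lexicographically smallest concept-index set.
#'
#' @param feature_table a `group_feature_table`.
#' @param beam_width optional cap on the number of surviving sets per
#'   iteration (default `Inf` = the exact rule); when finite, survivors
#'   are kept in order of decreasing accuracy then lexicographic set
#'   order, which keeps the search deterministic.
#' @return list with `selected` (concept indices), `selected_labels`,
#'   `accuracy`, and `trace` (data.frame: iteration, set, accuracy for
#'   every surviving set).
#' @export
stepwise_concept_selection <- function(feature_table, beam_width = Inf) {
  n <- length(feature_table$concepts)
  if (n < 1) stop("need at least one concept")
  cache <- new.env(hash = TRUE)
  acc_of <- function(set) {
    key <- paste(set, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    a <- classify_group_membership(feature_table, set)$accuracy
    assign(key, a, envir = cache)
    a
  }
  set_key <- function(set) paste(sprintf("%04d", set), collapse = ",")

  # iteration 1: best single concept(s)
  acc1 <- vapply(seq_len(n), function(i) acc_of(i), 1.0)
  best <- max(acc1)
  survivors <- lapply(which(acc1 == best), identity)
  trace <- data.frame(iteration = 1L,
                      set = vapply(survivors, function(s) paste(s, collapse = ","), ""),
                      accuracy = rep(best, length(survivors)))
  final_sets <- survivors
  final_accs <- rep(best, length(survivors))
  it <- 1L
  while (TRUE) {
    it <- it + 1L
    ext <- list(); ext_acc <- numeric(0); seen <- new.env(hash = TRUE)
    for (s in survivors) {
      for (cc in setdiff(seq_len(n), s)) {
        cand <- sort(c(s, cc))
        key <- set_key(cand)
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        ext[[length(ext) + 1]] <- cand
        ext_acc <- c(ext_acc, acc_of(cand))
      }
    }
    if (!length(ext) || max(ext_acc) < best) break
    keep <- which(ext_acc >= best)
    ord <- keep[order(-ext_acc[keep],
                      vapply(ext[keep], set_key, ""))]
    if (is.finite(beam_width) && length(ord) > beam_width) {
      ord <- ord[seq_len(beam_width)]
    }
    survivors <- ext[ord]
    best <- max(ext_acc)
    final_sets <- survivors
    final_accs <- ext_acc[ord]
    trace <- rbind(trace, data.frame(
      iteration = it,
      set = vapply(survivors, function(s) paste(s, collapse = ","), ""),
      accuracy = ext_acc[ord]))
    if (length(survivors[[1]]) == n) break
  }
  top <- which(final_accs == max(final_accs))
  pick <- top[order(vapply(final_sets[top], set_key, ""))][1]
  sel <- final_sets[[pick]]
  list(selected = sel,
       selected_labels = feature_table$concepts[sel],
       accuracy = final_accs[pick],
       trace = trace)
}
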