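#' Run the full neurosemantic analysis pipeline on a synthetic cohort
#'
#' Executes the configured stages in order: `simulate` (ground truth,
#' cohort, ratings), `decoding` (within-participant GNB cross-validation,
#' cross-participant decoding, category-mean classification, optional
#' permutation test), `factors` (two-level factor analysis on the most
#' accurately classified participants, voxel-factor assignment, spatial
#' clustering, secondary factor analysis, ratings validation, word-length
#' check), `forward_model` (ratings-to-activation regression with
#' leave-one-concept-out evaluation on the held-out participants), and
#' `group_compare` (faculty-vs-student classification on the shared
#' elementary concepts with stepwise concept selection).
#'
#' Stage dependencies are validated before any work: `decoding` requires
#' `simulate`; `factors` requires `decoding`; `forward_model` requires
#' `factors`; `group_compare` requires both groups to be simulated.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list with one element per executed stage
#'   plus the resolved configuration and seeds. If `config$output_dir` is
#'   set, a JSON report and TSV artifacts are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stages <- config$stages
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages) {
      stop(sprintf("stage dependency violated: '%s' requires '%s'", stage, dep))
    }
  }
  need("decoding", "simulate")
  need("factors", "decoding")
  need("forward_model", "factors")
  need("group_compare", "decoding")
  if ("group_compare" %in% stages &&
      (config$n_students < 2 || config$n_faculty < 2)) {
    stop("stage dependency violated: 'group_compare' requires at least two participants per group")
  }
  report <- list(config = unclass(config))
  if (!"simulate" %in% stages) stop("the pipeline currently requires the simulate stage")

  ## simulate ---------------------------------------------------------------
  geometry <- make_geometry(config$grid_shape, config$voxel_size_mm)
  gt <- sample_ground_truth(clusters_per_dimension = config$clusters_per_dimension,
                            cluster_size_range = config$cluster_size_range,
                            noise_sd = config$noise_sd,
                            participant_sd = config$participant_sd,
                            group_effect = config$group_effect,
                            geometry = geometry,
                            seed = config$seed)
  cohort <- simulate_cohort(gt, config$n_faculty, config$n_students,
                            config$n_presentations)
  ratings <- simulate_ratings(gt, n_raters = config$n_raters,
                              rater_noise_sd = config$rater_noise_sd)
  faculty <- which(vapply(cohort, function(d) d$group, "") == "faculty")
  report$simulate <- list(n_faculty = config$n_faculty,
                          n_students = config$n_students,
                          n_voxels = geometry$n_voxels,
                          dimensions = gt$dimension_names,
                          seed = gt$seed)
  out <- list(gt = gt, cohort = cohort, ratings = ratings)

  ## decoding ---------------------------------------------------------------
  if ("decoding" %in% stages) {
    within <- vapply(faculty, function(i) {
      within_participant_cv(cohort[[i]],
                            n_features = config$n_decoding_features)$mean_accuracy
    }, 1.0)
    top <- faculty[order(-within)][seq_len(min(config$n_fa_participants,
                                               length(faculty)))]
    cross_mean <- NA_real_
    cross <- NULL
    if (length(faculty) >= 3) {
      cross <- cross_participant_cv(cohort[faculty],
                                    n_features = config$n_decoding_features)
      cross_mean <- cross$mean_accuracy
    }
    category <- NULL
    if (!is.null(gt$concept_categories)) {
      category <- classify_category_means(cohort[faculty], gt$concept_categories)
    }
    perm <- NULL
    if (config$n_permutations > 0) {
      best <- faculty[which.max(within)]
      stat_fn <- function(d) {
        suppressMessages(within_participant_cv(
          d, n_features = config$n_decoding_features,
          fold_scheme = "disjoint"))$mean_accuracy
      }
      observed <- stat_fn(cohort[[best]])
      perm <- permutation_test(observed, cohort[[best]], stat_fn,
                               n_permutations = config$n_permutations,
                               seed = derive_seed(config$seed, 51))
    }
    report$decoding <- list(
      within_participant = list(per_participant = unname(within),
                                mean = mean(within),
                                range = range(within)),
      fa_participants = top,
      cross_participant = list(mean = cross_mean,
                               per_participant = if (is.null(cross)) NULL
                                                 else unname(cross$fold_accuracy)),
      category_means = if (is.null(category)) NULL else
        list(grand_mean = category$grand_mean,
             per_participant = unname(category$per_participant)),
      permutation = if (is.null(perm)) NULL else
        list(observed = perm$observed, p_value = perm$p_value,
             n_permutations = perm$n_permutations))
    out$within <- within
    out$top <- top
  }

  ## factors ----------------------------------------------------------------
  if ("factors" %in% stages) {
    ind <- lapply(out$top, function(i) {
      suppressWarnings(suppressMessages(
        individual_level_fa(cohort[[i]], n_per_lobe = config$n_per_lobe,
                            n_factors = config$n_factors_individual)))
    })
    group_sol <- suppressMessages(
      group_level_fa(ind, variance_threshold = config$variance_threshold))
    M3 <- Reduce(`+`, lapply(out$top, function(i) {
      presentation_mean(cohort[[i]]$psc)
    })) / length(out$top)
    loadings <- voxel_factor_loadings(M3, group_sol$scores)
    assignment <- assign_voxels_to_factors(loadings, config$loading_threshold)
    cluster_map <- extract_clusters(assignment, geometry,
                                    config$min_cluster_size,
                                    config$connectivity)
    truth_match <- match_factors_to_truth(group_sol, gt)

    # match retained factors to the rated dimensions and orient their signs
    rat_cor <- stats::cor(ratings, group_sol$scores)
    rat_match <- greedy_match(rat_cor)
    sem_scores <- matrix(NA_real_, nrow(group_sol$scores), nrow(rat_match),
                         dimnames = list(rownames(group_sol$scores),
                                         rownames(rat_cor)[rat_match$row]))
    for (q in seq_len(nrow(rat_match))) {
      sem_scores[, q] <- group_sol$scores[, rat_match$col[q]] *
        sign(rat_match$r[q])
    }
    val_all <- correlate_scores_with_ratings(sem_scores, ratings, "all")
    val_ext <- correlate_scores_with_ratings(sem_scores, ratings, "extremes")

    # word-length validity check
    wl <- as.numeric(scale(nchar(gt$concept_labels)))
    wl_cor <- as.numeric(stats::cor(wl, group_sol$scores))
    wl_factor <- which.max(abs(wl_cor))
    wl_voxels <- which(!is.na(assignment) & assignment == wl_factor)
    wl_cluster_voxels <- unlist(lapply(cluster_map$clusters, function(cl) {
      if (cl$factor == wl_factor) cl$voxels else NULL
    }))
    wl_frac <- if (length(wl_cluster_voxels)) {
      mean(geometry$lobe[wl_cluster_voxels] == "occipital")
    } else NA_real_

    # secondary FA on input columns not associated with any retained factor
    S <- stack_individual_scores(ind)
    assoc <- apply(abs(group_sol$loadings), 1, max)
    residual <- S[, assoc <= config$loading_threshold, drop = FALSE]
    secondary <- suppressWarnings(suppressMessages(
      secondary_fa(residual, config$variance_threshold)))

    report$factors <- list(
      n_retained = ncol(group_sol$loadings),
      variance_explained = unname(group_sol$variance_explained),
      truth_match = truth_match,
      ratings_validation_all = val_all,
      ratings_validation_extremes = val_ext,
      word_length = list(factor = wl_factor, r = abs(wl_cor[wl_factor]),
                         occipital_fraction = wl_frac),
      n_clusters = length(cluster_map$clusters),
      n_secondary_factors = ncol(secondary$loadings))
    out$group_sol <- group_sol
    out$cluster_map <- cluster_map
    out$sem_scores <- sem_scores
    out$rat_match <- rat_match
    out$ind <- ind
  }

  ## forward model ----------------------------------------------------------
  if ("forward_model" %in% stages) {
    test_idx <- setdiff(faculty, out$top)
    if (!length(test_idx)) test_idx <- faculty
    mean_ds <- average_datasets(cohort[test_idx])
    sem_factors <- out$rat_match$col
    sem_clusters <- Filter(function(cl) cl$factor %in% sem_factors,
                           out$cluster_map$clusters)
    if (!length(sem_clusters)) stop("no semantic-factor clusters available for the forward model")
    acts <- suppressMessages(suppressWarnings(
      cluster_mean_activation(mean_ds, sem_clusters,
                              n_voxels = config$forward_n_voxels,
                              cuboid_radius = config$cuboid_radius)))
    rownames(acts) <- gt$concept_labels
    fwd <- suppressWarnings(loo_evaluate(unclass(ratings), acts))
    report$forward_model <- list(
      n_clusters = ncol(acts),
      n_excluded = nrow(attr(acts, "excluded")),
      mean_r2 = fwd$mean_r2,
      rank_accuracy = fwd$rank_accuracy$mean)
    out$forward <- fwd
  }

  ## group comparison -------------------------------------------------------
  if ("group_compare" %in% stages) {
    gc_res <- run_group_comparison(cohort, gt, config)
    report$group_compare <- list(
      n_shared_concepts = length(gc_res$shared),
      n_union_clusters = length(gc_res$union),
      accuracy = gc_res$classification$accuracy,
      stepwise = list(selected = gc_res$stepwise$selected_labels,
                      accuracy = gc_res$stepwise$accuracy,
                      n_iterations = max(gc_res$stepwise$trace$iteration)))
    out$group_compare <- gc_res
  }

  report$seed <- config$seed
  res <- structure(report, class = "pipeline_report")
  attr(res, "objects") <- out
  if (!is.null(config$output_dir)) write_pipeline_artifacts(res, config$output_dir)
  res
}

# The faculty-vs-student comparison on the shared elementary concepts.
run_group_comparison <- function(cohort, gt, config) {
  tab <- physics_concepts()
  shared <- intersect(tab$label[tab$elementary], gt$concept_labels)
  if (!length(shared)) stop("no shared elementary concepts available")
  groups <- vapply(cohort, function(d) d$group, "")
  sub <- lapply(cohort, subset_concepts, shared)

  fa_for <- function(idx) {
    lapply(idx, function(i) {
      suppressWarnings(suppressMessages(
        individual_level_fa(sub[[i]], n_per_lobe = config$n_per_lobe,
                            n_factors = min(config$n_factors_individual,
                                            length(shared) - 2))))
    })
  }
  ind_a <- fa_for(which(groups == "faculty"))
  ind_b <- fa_for(which(groups == "student"))
  sol_a <- suppressMessages(group_level_fa(ind_a, config$variance_threshold))
  sol_b <- suppressMessages(group_level_fa(ind_b, config$variance_threshold))
  keep_top <- function(sol, k) {
    ord <- order(-sol$variance_explained)[seq_len(min(k, ncol(sol$loadings)))]
    sol$loadings <- sol$loadings[, ord, drop = FALSE]
    sol$scores <- sol$scores[, ord, drop = FALSE]
    sol$variance_explained <- sol$variance_explained[ord]
    sol
  }
  sol_a <- keep_top(sol_a, config$n_factors_group_compare)
  sol_b <- keep_top(sol_b, config$n_factors_group_compare)
  al <- align_factors(list(sol_a, sol_b))[[2]]
  b_to_a <- stats::setNames(al$ref_factor, al$factor)

  maps_for <- function(idx, sol, remap = NULL) {
    lapply(idx, function(i) {
      L <- voxel_factor_loadings(presentation_mean(sub[[i]]$psc), sol$scores)
      a <- assign_voxels_to_factors(L, config$loading_threshold)
      cm <- extract_clusters(a, gt$geometry, config$min_cluster_size,
                             config$connectivity)
      if (!is.null(remap)) {
        next_id <- max(c(0, remap)) + 1
        cm$clusters <- lapply(cm$clusters, function(cl) {
          hit <- remap[as.character(cl$factor)]
          cl$factor <- if (!is.na(hit)) unname(hit) else next_id + cl$factor
          cl
        })
      }
      cm
    })
  }
  maps_a <- maps_for(which(groups == "faculty"), sol_a)
  maps_b <- maps_for(which(groups == "student"), sol_b, remap = b_to_a)

  un <- union_factor_clusters(maps_a, maps_b,
                              min_participants = config$min_cluster_participants)
  ft <- suppressMessages(suppressWarnings(
    build_group_features(sub, un, shared, n_voxels = config$group_n_voxels)))
  cls <- classify_group_membership(ft)
  sw <- stepwise_concept_selection(ft, beam_width = config$stepwise_beam_width)
  list(shared = shared, union = un, feature_table = ft,
       classification = cls, stepwise = sw,
       solutions = list(faculty = sol_a, student = sol_b))
}

#' Restrict a dataset to a concept subset
#'
#' @param dataset an `activation_dataset`.
#' @param concepts concept labels or indices to keep.
#' @return the restricted `activation_dataset`.
#' @export
subset_concepts <- function(dataset, concepts) {
  idx <- if (is.character(concepts)) match(concepts, dataset$concept_labels)
         else as.integer(concepts)
  if (any(is.na(idx))) stop("unknown concept(s) in subset")
  dataset$psc <- dataset$psc[idx, , , drop = FALSE]
  dataset$concept_labels <- dataset$concept_labels[idx]
  dataset
}

# Write the JSON report plus TSV artifacts for a pipeline run.
write_pipeline_artifacts <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- attr(report, "objects")
  clean <- unclass(report)
  attr(clean, "objects") <- NULL
  clean$config$output_dir <- NULL   # path-dependent; keep reports comparable
  jsonlite::write_json(clean, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(obj$group_sol)) {
    write_factor_scores_tsv(obj$group_sol$scores,
                            file.path(output_dir, "group_factor_scores.tsv"))
    write_clusters_tsv(obj$cluster_map, file.path(output_dir, "clusters.tsv"))
  }
  if (!is.null(obj$within)) {
    utils::write.table(
      data.frame(participant = seq_along(obj$within),
                 mean_normalized_rank_accuracy = obj$within),
      file.path(output_dir, "within_participant_cv.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(obj$group_compare)) {
    utils::write.table(obj$group_compare$stepwise$trace,
                       file.path(output_dir, "stepwise_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(output_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  if (!is.null(x$decoding)) {
    cat(sprintf("  within-participant decoding: %.3f\n",
                x$decoding$within_participant$mean))
    if (!is.na(x$decoding$cross_participant$mean)) {
      cat(sprintf("  cross-participant decoding:  %.3f\n",
                  x$decoding$cross_participant$mean))
    }
  }
  if (!is.null(x$factors)) {
    cat(sprintf("  retained group factors: %d (clusters: %d)\n",
                x$factors$n_retained, x$factors$n_clusters))
  }
  if (!is.null(x$forward_model)) {
    cat(sprintf("  forward model: mean R^2 %.3f, rank accuracy %.3f\n",
                x$forward_model$mean_r2, x$forward_model$rank_accuracy))
  }
  if (!is.null(x$group_compare)) {
    cat(sprintf("  group classification accuracy: %.3f\n",
                x$group_compare$accuracy))
  }
  invisible(x)
}
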