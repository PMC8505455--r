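#' Within-participant concept decoding by cross-validated GNB
#'
#' Cross-validates a Gaussian naive Bayes concept classifier over
#' presentations of a single participant. In each fold two presentations
#' are held out: voxel stability and the top-`n_features` feature selection
#' are computed from the training presentations only (no leakage), the
#' classifier is trained on the individual training presentations of every
#' concept, and tested on the mean of the held-out presentations. By
#' default all `choose(P, 2)` test pairs are used; a disjoint-pairs scheme
#' is available behind `fold_scheme`.
#'
#' @param dataset an `activation_dataset` with >= 3 presentations.
#' @param n_features number of stable voxels used as features (default
#'   120, selected whole-brain; per-lobe selection is available through
#'   [select_stable_voxels()] directly).
#' @param exclude_region optional lobe name whose voxels are removed from
#'   the candidate set (e.g. `"occipital"` to suppress the visual
#'   word-form confound).
#' @param fold_scheme `"all_pairs"` (default) or `"disjoint"`.
#' @param details keep per-fold artifacts (selected voxels, model, test
#'   presentations) for leakage audits.
#' @return An object of class `cv_result`: list with `mean_accuracy`,
#'   `fold_accuracy`, `folds` (test presentation pairs), `n_features`, and
#'   optionally `details`.
#' @export
within_participant_cv <- function(dataset, n_features = 120,
                                  exclude_region = NULL,
                                  fold_scheme = c("all_pairs", "disjoint"),
                                  details = FALSE) {
  fold_scheme <- match.arg(fold_scheme)
  psc <- dataset$psc
  C <- dim(psc)[1]; P <- dim(psc)[2]; V <- dim(psc)[3]
  if (P < 3) stop("need at least 3 presentations for a 2-presentation test set")
  labels <- dataset$concept_labels %||% as.character(seq_len(C))
  cand <- seq_len(V)
  if (!is.null(exclude_region)) {
    if (!exclude_region %in% LOBE_NAMES) stop("unknown region: ", exclude_region)
    cand <- which(dataset$geometry$lobe != exclude_region)
  }
  folds <- if (fold_scheme == "all_pairs") {
    utils::combn(P, 2)
  } else {
    matrix(seq_len(P - P %% 2), nrow = 2)
  }
  fold_acc <- numeric(ncol(folds))
  det <- if (details) vector("list", ncol(folds)) else NULL
  for (q in seq_len(ncol(folds))) {
    test_p <- folds[, q]
    train_p <- setdiff(seq_len(P), test_p)
    stab <- voxel_stability(psc[, train_p, cand, drop = FALSE])
    sel <- cand[select_stable_voxels(stab, min(n_features, length(cand)))]
    Xtr <- do.call(rbind, lapply(train_p, function(p) {
      matrix(psc[, p, sel], nrow = C)
    }))
    ytr <- rep(labels, times = length(train_p))
    Xte <- (matrix(psc[, test_p[1], sel], nrow = C) +
            matrix(psc[, test_p[2], sel], nrow = C)) / 2
    model <- train_gnb(Xtr, ytr)
    scores <- predict(model, Xte)
    fold_acc[q] <- rank_accuracy(scores, labels)$mean
    if (details) det[[q]] <- list(test_presentations = test_p,
                                  selected_voxels = sel, model = model)
  }
  structure(list(mean_accuracy = mean(fold_acc),
                 fold_accuracy = fold_acc,
                 folds = folds,
                 n_features = n_features,
                 details = det),
            class = "cv_result")
}

#' Cross-participant concept decoding (leave-one-participant-out)
#'
#' Tests the commonality of concept signatures across participants: in
#' each fold one participant is left out, every participant's data is
#' averaged over presentations, the `n_features` voxels with the most
#' consistent concept profiles across the training participants are
#' selected ([cross_participant_consistency()]), a GNB classifier is
#' trained on the training participants' per-participant concept means
#' (one exemplar per concept per participant), and the left-out
#' participant's 45 concept means are classified.
#'
#' @param datasets list of >= 3 `activation_dataset`s on a shared geometry
#'   with identical concept sets.
#' @param n_features number of consistent voxels used as features.
#' @param details keep per-fold artifacts for leakage audits.
#' @return a `cv_result` whose `fold_accuracy` holds one normalized rank
#'   accuracy per left-out participant.
#' @export
cross_participant_cv <- function(datasets, n_features = 120, details = FALSE) {
  n <- length(datasets)
  if (n < 3) stop("need at least 3 participants")
  labels <- datasets[[1]]$concept_labels %||%
    as.character(seq_len(dim(datasets[[1]]$psc)[1]))
  for (d in datasets) {
    if (!identical(d$concept_labels, datasets[[1]]$concept_labels)) {
      stop("mismatched concept sets across participants")
    }
    if (dim(d$psc)[3] != dim(datasets[[1]]$psc)[3]) {
      stop("participants must share the voxel grid")
    }
  }
  M <- lapply(datasets, function(d) presentation_mean(d$psc))
  fold_acc <- numeric(n)
  det <- if (details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    cons <- cross_participant_consistency(M[train])
    sel <- select_stable_voxels(cons, min(n_features, length(cons)))
    Xtr <- do.call(rbind, lapply(train, function(j) M[[j]][, sel, drop = FALSE]))
    ytr <- rep(labels, times = length(train))
    model <- train_gnb(Xtr, ytr)
    scores <- predict(model, M[[i]][, sel, drop = FALSE])
    fold_acc[i] <- rank_accuracy(scores, labels)$mean
    if (details) det[[i]] <- list(left_out = i, selected_voxels = sel,
                                  model = model)
  }
  structure(list(mean_accuracy = mean(fold_acc),
                 fold_accuracy = fold_acc,
                 folds = seq_len(n),
                 n_features = n_features,
                 details = det),
            class = "cv_result")
}

#' Permutation test for decoding accuracy
#'
#' Permutes the concept labels within each participant — independently for
#' every presentation, so the association between a concept label and its
#' activation signature is destroyed rather than merely relabelled —
#' re-runs the full cross-validation statistic, and reports the add-one
#' permutation p-value `(1 + #[perm >= observed]) / (1 + n_permutations)`,
#' which is never zero.
#'
#' @param observed the observed mean accuracy.
#' @param data an `activation_dataset` or list of them.
#' @param stat_fn function mapping `data` (same shape as supplied) to a
#'   scalar accuracy, e.g.
#'   `function(d) within_participant_cv(d)$mean_accuracy`.
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed; permutation `r` derives its own stream so the
#'   test is reproducible and parallelizable.
#' @return list with `p_value`, `observed`, `perm_stats`, `n_permutations`.
#' @export
permutation_test <- function(observed, data, stat_fn, n_permutations = 1000,
                             seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  single <- inherits(data, "activation_dataset")
  dl <- if (single) list(data) else data
  perm_stats <- numeric(n_permutations)
  for (r in seq_len(n_permutations)) {
    set.seed(derive_seed(seed, 41, r))
    pd <- lapply(dl, function(d) {
      C <- dim(d$psc)[1]
      for (p in seq_len(dim(d$psc)[2])) {
        d$psc[, p, ] <- d$psc[sample(C), p, ]
      }
      dimnames(d$psc)[[1]] <- d$concept_labels
      d
    })
    perm_stats[r] <- stat_fn(if (single) pd[[1]] else pd)
  }
  list(p_value = (1 + sum(perm_stats >= observed)) / (1 + n_permutations),
       observed = observed,
       perm_stats = perm_stats,
       n_permutations = n_permutations)
}

#' Classify category mean signatures (e.g. classical vs post-classical)
#'
#' Within each participant, leave-one-presentation-out: the two categories'
#' mean activation signatures are computed from the training presentations,
#' the held-out presentation's category means are classified by nearest
#' training signature under correlation distance, and the per-participant
#' accuracy is the fraction of correct decisions over presentations and
#' categories. The grand mean over participants is reported.
#'
#' @param datasets an `activation_dataset` or list of them.
#' @param categories character/factor of length n_concepts with exactly two
#'   levels, each covering >= 2 concepts.
#' @return list with `grand_mean`, `per_participant`.
#' @export
classify_category_means <- function(datasets, categories) {
  single <- inherits(datasets, "activation_dataset")
  dl <- if (single) list(datasets) else datasets
  cats <- factor(categories)
  if (nlevels(cats) != 2) stop("categories must have exactly two levels")
  if (any(table(cats) < 2)) {
    stop("category with fewer than 2 concepts: ",
         paste(names(which(table(cats) < 2)), collapse = ", "))
  }
  idx <- split(seq_along(cats), cats)
  per <- vapply(dl, function(d) {
    psc <- d$psc
    P <- dim(psc)[2]
    correct <- 0L; total <- 0L
    for (t in seq_len(P)) {
      train_p <- setdiff(seq_len(P), t)
      train_sig <- lapply(idx, function(ii) {
        colMeans(presentation_mean(psc, train_p)[ii, , drop = FALSE])
      })
      for (a in 1:2) {
        test_sig <- colMeans(matrix(psc[idx[[a]], t, ], nrow = length(idx[[a]])))
        rs <- vapply(train_sig, function(s) stats::cor(test_sig, s), 1.0)
        correct <- correct + as.integer(which.max(rs) == a)
        total <- total + 1L
      }
    }
    correct / total
  }, 1.0)
  list(grand_mean = mean(per), per_participant = per)
}

#' Write a cross-validation report as TSV
#' @param cv a `cv_result`.
#' @param path output path.
#' @export
write_cv_report_tsv <- function(cv, path) {
  df <- data.frame(fold = seq_along(cv$fold_accuracy),
                   mean_normalized_rank_accuracy = cv$fold_accuracy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean normalized rank accuracy %.4f over %d fold(s)\n",
              x$mean_accuracy, length(x$fold_accuracy)))
  invisible(x)
}
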