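#' Simulate one participant's activation dataset
#'
#' Generates a concepts x presentations x voxels percent-signal-change
#' tensor from a planted ground truth. The expected activation of voxel `v`
#' for concept `c` is the inner product of the concept's latent scores with
#' the voxel's loadings, after a participant-specific Gaussian perturbation
#' of the nonzero loadings; independent Gaussian presentation noise is then
#' added to every (concept, presentation, voxel) cell:
#' `psc[c, p, v] = sum_d score[c, d] * (loading[v, d] + pert[v, d]) + N(0, noise_sd)`.
#'
#' The simulation is deterministic given `(gt$seed, participant_index)`, so
#' a participant can be regenerated independently of cohort size.
#'
#' @param gt a [sample_ground_truth()] object.
#' @param participant_index positive integer identifying the participant.
#' @param n_presentations number of stimulus presentations (>= 2).
#' @param group `"faculty"` or `"student"`; selects the group's loading map.
#' @return An object of class `activation_dataset`: list with
#'   `participant_id`, `group`, `psc` (concepts x presentations x voxels),
#'   `concept_labels` and `geometry`.
#' @export
simulate_participant <- function(gt, participant_index, n_presentations = 6,
                                 group = c("faculty", "student")) {
  group <- match.arg(group)
  if (n_presentations < 2) stop("n_presentations must be at least 2")
  L <- if (group == "faculty") gt$loading_map else gt$loading_map_student
  C <- nrow(gt$concept_scores)
  V <- nrow(L)

  set.seed(derive_seed(gt$seed, 21, participant_index))
  mask <- L != 0
  pert <- matrix(0, V, ncol(L))
  if (gt$participant_sd > 0 && any(mask)) {
    pert[mask] <- stats::rnorm(sum(mask), 0, gt$participant_sd)
  }
  signal <- gt$concept_scores %*% t(L + pert)     # concepts x voxels

  set.seed(derive_seed(gt$seed, 22, participant_index))
  noise <- array(stats::rnorm(C * n_presentations * V, 0, gt$noise_sd),
                 dim = c(C, n_presentations, V))
  psc <- aperm(array(signal, dim = c(C, V, n_presentations)), c(1, 3, 2)) + noise
  dimnames(psc) <- list(gt$concept_labels, NULL, NULL)

  structure(list(participant_id = as.integer(participant_index),
                 group = group,
                 psc = psc,
                 concept_labels = gt$concept_labels,
                 geometry = gt$geometry),
            class = "activation_dataset")
}

#' Simulate a multi-participant cohort
#'
#' Faculty participants receive indices `1..n_faculty`, students
#' `n_faculty+1 .. n_faculty+n_students`; all share the ground truth's
#' geometry (the post-normalization assumption required for
#' cross-participant classification).
#'
#' @inheritParams simulate_participant
#' @param n_faculty,n_students group sizes; their sum must be >= 1.
#' @return list of `activation_dataset` objects.
#' @export
simulate_cohort <- function(gt, n_faculty = 10, n_students = 9,
                            n_presentations = 6) {
  if (n_faculty + n_students < 1) stop("cohort must contain at least one participant")
  out <- vector("list", n_faculty + n_students)
  for (i in seq_len(n_faculty)) {
    out[[i]] <- simulate_participant(gt, i, n_presentations, "faculty")
  }
  for (j in seq_len(n_students)) {
    out[[n_faculty + j]] <- simulate_participant(gt, n_faculty + j,
                                                 n_presentations, "student")
  }
  out
}

#' Simulate expert ratings of concepts on semantic dimensions
#'
#' Emulates a panel of raters scoring each concept on each interpreted
#' dimension with a 7-point scale. Each rater's rating is an affine map of
#' the true latent score (+/- 2 sd mapping to the scale endpoints 1 and 7,
#' i.e. `4 + 1.5 * z`), plus Gaussian rater noise, rounded and clipped to
#' the integers 1..7; the returned cell is the mean over raters.
#'
#' @param gt a [sample_ground_truth()] object.
#' @param rated_dimensions dimensions to rate; must be a subset of
#'   `gt$dimension_names` excluding the `"word_length"` nuisance dimension.
#'   Defaults to all non-nuisance dimensions.
#' @param n_raters number of raters (>= 1).
#' @param rater_noise_sd sd of the rater noise on the latent (z) scale.
#' @param seed seed for the rater noise; defaults to the ground truth seed.
#' @return A `ratings_matrix`: numeric matrix (concepts x dimensions) with
#'   values in [1, 7] and attribute `rater_count`.
#' @export
simulate_ratings <- function(gt, rated_dimensions = NULL, n_raters = 6,
                             rater_noise_sd = 1.0, seed = gt$seed) {
  if (n_raters < 1) stop("n_raters must be at least 1")
  if (is.null(rated_dimensions)) {
    rated_dimensions <- setdiff(gt$dimension_names, "word_length")
  }
  if ("word_length" %in% rated_dimensions) {
    stop("the word_length nuisance dimension is not rated")
  }
  if (!all(rated_dimensions %in% gt$dimension_names)) {
    stop("rated_dimensions must be a subset of gt$dimension_names")
  }
  truth <- gt$concept_scores[, rated_dimensions, drop = FALSE]
  acc <- matrix(0, nrow(truth), ncol(truth))
  for (r in seq_len(n_raters)) {
    set.seed(derive_seed(seed, 31, r))
    noise <- matrix(stats::rnorm(length(truth), 0, rater_noise_sd),
                    nrow(truth), ncol(truth))
    acc <- acc + pmin(7, pmax(1, round(4 + 1.5 * truth + noise)))
  }
  values <- acc / n_raters
  dimnames(values) <- dimnames(truth)
  structure(values, rater_count = as.integer(n_raters),
            class = c("ratings_matrix", "matrix", "array"))
}

#' Render a dataset as raw per-voxel timecourses
#'
#' Optional timecourse view of an activation dataset for exercising
#' [compute_psc()]: trials are laid out sequentially (4 s stimulus + 6 s
#' rest at a 1 s sampling interval) and the hemodynamic response window
#' (offset 5 s from onset, 4 samples long) of each trial is set so that the
#' percent signal change relative to `baseline` equals the dataset's PSC
#' value exactly.
#'
#' @param dataset an `activation_dataset`.
#' @param baseline baseline signal level (arbitrary scanner units, > 0).
#' @param window_offset_s,window_len_s response window geometry in seconds.
#' @param trial_len_s spacing between consecutive trial onsets.
#' @return list with `series` (time x voxels matrix), `onsets` (1-based
#'   sample index per trial), `events` (data.frame of concept and
#'   presentation per trial) and `baseline`.
#' @export
simulate_timecourse <- function(dataset, baseline = 100,
                                window_offset_s = 5, window_len_s = 4,
                                trial_len_s = 10) {
  psc <- dataset$psc
  C <- dim(psc)[1]; P <- dim(psc)[2]; V <- dim(psc)[3]
  n_trials <- C * P
  n_time <- n_trials * trial_len_s + window_offset_s + window_len_s
  series <- matrix(baseline, n_time, V)
  onsets <- integer(n_trials)
  events <- data.frame(concept = integer(n_trials), presentation = integer(n_trials))
  t0 <- 1L
  tr <- 1L
  for (p in seq_len(P)) {
    for (cc in seq_len(C)) {
      onsets[tr] <- t0
      events$concept[tr] <- cc
      events$presentation[tr] <- p
      rows <- t0 + window_offset_s + seq_len(window_len_s) - 1
      series[rows, ] <- rep(baseline * (1 + psc[cc, p, ] / 100),
                            each = window_len_s)
      t0 <- t0 + as.integer(trial_len_s)
      tr <- tr + 1L
    }
  }
  list(series = series, onsets = onsets, events = events, baseline = baseline)
}

#' Average several datasets into a grand-mean dataset
#'
#' Voxel-wise mean of the PSC tensors of multiple participants sharing a
#' geometry and concept set (used e.g. to build the grand-mean dataset on
#' which the forward model's cluster features are computed).
#'
#' @param datasets list of `activation_dataset` objects.
#' @return an `activation_dataset` whose `psc` is the element-wise mean.
#' @export
average_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  psc <- datasets[[1]]$psc * 0
  for (d in datasets) {
    if (!identical(dim(d$psc), dim(psc))) stop("datasets must share dimensions")
    psc <- psc + d$psc
  }
  out <- datasets[[1]]
  out$psc <- psc / length(datasets)
  out$participant_id <- NA_integer_
  out
}

#' @export
print.activation_dataset <- function(x, ...) {
  d <- dim(x$psc)
  cat(sprintf("activation_dataset: participant %s (%s), %d concepts x %d presentations x %d voxels\n",
              x$participant_id, x$group, d[1], d[2], d[3]))
  invisible(x)
}
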