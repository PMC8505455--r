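#' The packaged physics concept table
#'
#' The 45 physics concepts used as the default stimulus set, with their
#' classical vs. post-classical tag and a flag marking the 15 elementary
#' concepts shared between the expert and student cohorts.
#'
#' @return data.frame with columns `label`, `category`
#'   (`"classical"`/`"post-classical"`) and `elementary` (logical).
#' @export
physics_concepts <- function() {
  path <- system.file("extdata", "physics_concepts.tsv", package = "neurosem")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$elementary <- as.logical(df$elementary)
  df
}

#' Sample a synthetic ground truth for concept-evoked activation
#'
#' Draws the latent structure that the analysis pipeline is meant to
#' recover: per-concept scores on a set of latent semantic dimensions,
#' spatially clustered voxel loadings planted inside anatomically labelled
#' lobes, and the noise/group parameters used by [simulate_participant()].
#'
#' One dimension is the designated `"word_length"` nuisance dimension: its
#' clusters are planted only in the occipital partition and, when concept
#' labels are supplied, its concept scores are the z-scored character counts
#' of the labels (emulating low-level visual encoding of the printed word).
#' When `concept_categories` are supplied, the `"classical_postclassical"`
#' dimension (if present) is the z-scored binary category contrast.
#'
#' @param n_concepts number of stimulus concepts (>= 2).
#' @param dimension_names names of the latent dimensions; must include
#'   `"word_length"` for the nuisance dimension to be planted.
#' @param clusters_per_dimension number of spatial clusters planted per
#'   dimension. Non-nuisance clusters cycle over the three non-occipital
#'   lobes so each semantic dimension is expressed in several lobes.
#' @param cluster_size_range integer range (min >= 2) of cluster sizes;
#'   each planted cluster is a face-connected set of voxels grown inside a
#'   single lobe.
#' @param noise_sd presentation-level Gaussian noise sd, in percent signal
#'   change units.
#' @param participant_sd sd of the per-participant perturbation applied to
#'   nonzero loadings.
#' @param group_effect number of clusters per semantic dimension that are
#'   relocated (within the same lobe) for the student group, creating a
#'   topographic group difference; 0 makes the groups identical.
#' @param geometry a [make_geometry()] object.
#' @param concept_labels,concept_categories optional label / category
#'   vectors; for the default 45 concepts they are taken from
#'   [physics_concepts()].
#' @param seed integer master seed; all randomness is derived from it.
#' @return An object of class `ground_truth` with fields `concept_scores`
#'   (concepts x dimensions, columns z-scored), `dimension_names`,
#'   `loading_map` and `loading_map_student` (voxels x dimensions),
#'   `cluster_spec` and `cluster_spec_student`, `noise_sd`,
#'   `participant_sd`, `group_effect`, `geometry`, `concept_labels`,
#'   `concept_categories` and `seed`.
#' @export
sample_ground_truth <- function(n_concepts = 45,
                                dimension_names = c("measurable_magnitude",
                                                    "mathematical_formulation",
                                                    "periodicity",
                                                    "classical_postclassical",
                                                    "word_length"),
                                clusters_per_dimension = 3,
                                cluster_size_range = c(3L, 9L),
                                noise_sd = 0.1,
                                participant_sd = 0.1,
                                group_effect = 1,
                                geometry = make_geometry(),
                                concept_labels = NULL,
                                concept_categories = NULL,
                                seed = 1L) {
  if (n_concepts < 2) stop("n_concepts must be at least 2")
  cluster_size_range <- as.integer(round(cluster_size_range))
  if (length(cluster_size_range) != 2 || cluster_size_range[1] < 2 ||
      cluster_size_range[2] < cluster_size_range[1]) {
    stop("cluster_size_range must be an increasing pair with minimum >= 2")
  }
  if (is.null(concept_labels) && n_concepts == 45) {
    tab <- physics_concepts()
    concept_labels <- tab$label
    if (is.null(concept_categories)) concept_categories <- tab$category
  }
  if (!is.null(concept_labels) && length(concept_labels) != n_concepts) {
    stop("concept_labels must have length n_concepts")
  }

  set.seed(derive_seed(seed, 11))
  nd <- length(dimension_names)
  scores <- matrix(NA_real_, n_concepts, nd,
                   dimnames = list(concept_labels, dimension_names))
  for (d in seq_len(nd)) {
    nm <- dimension_names[d]
    raw <- if (identical(nm, "word_length") && !is.null(concept_labels)) {
      nchar(concept_labels)
    } else if (identical(nm, "classical_postclassical") &&
               !is.null(concept_categories)) {
      # binary contrast with a small jitter so the scores are not two-valued
      ifelse(concept_categories == "classical", 1, -1) +
        stats::rnorm(n_concepts, 0, 0.1)
    } else {
      stats::rnorm(n_concepts)
    }
    scores[, d] <- as.numeric(scale(raw))
  }

  nv <- geometry$n_voxels
  used <- logical(nv)

  sizes <- lapply(seq_len(nd), function(d) {
    sample(seq(cluster_size_range[1], cluster_size_range[2]),
           clusters_per_dimension, replace = TRUE)
  })
  lobes_for_dim <- function(d) {
    if (identical(dimension_names[d], "word_length")) {
      rep("occipital", clusters_per_dimension)
    } else {
      pool <- setdiff(LOBE_NAMES, "occipital")
      pool[((d - 1) + seq_len(clusters_per_dimension) - 1) %% length(pool) + 1]
    }
  }

  # capacity check before any growth
  req <- stats::aggregate(
    size ~ lobe,
    data = do.call(rbind, lapply(seq_len(nd), function(d) {
      data.frame(lobe = lobes_for_dim(d), size = sizes[[d]])
    })), FUN = sum)
  for (r in seq_len(nrow(req))) {
    cap <- sum(geometry$lobe == req$lobe[r])
    if (req$size[r] > cap) {
      stop(sprintf("requested clusters exceed capacity of lobe '%s' (%d > %d voxels)",
                   req$lobe[r], req$size[r], cap))
    }
  }

  grow_cluster <- function(lobe, size, used) {
    in_lobe <- geometry$lobe == lobe
    for (attempt in seq_len(200)) {
      free <- which(in_lobe & !used)
      if (length(free) < size) {
        stop(sprintf("requested clusters exceed capacity of lobe '%s'", lobe))
      }
      s <- free[sample.int(length(free), 1)]
      members <- s
      repeat {
        if (length(members) == size) return(sort(members))
        nb <- unique(unlist(lapply(members, function(v) face_neighbors(geometry, v))))
        nb <- setdiff(nb[in_lobe[nb] & !used[nb]], members)
        if (!length(nb)) break
        members <- c(members, nb[sample.int(length(nb), 1)])
      }
    }
    stop(sprintf("could not grow a cluster of size %d in lobe '%s'", size, lobe))
  }

  plant <- function(dims, used, relocate_from = NULL) {
    loading <- matrix(0, nv, nd, dimnames = list(NULL, dimension_names))
    spec <- vector("list", nd)
    names(spec) <- dimension_names
    for (d in dims) {
      lobes <- lobes_for_dim(d)
      cl <- vector("list", clusters_per_dimension)
      for (ci in seq_len(clusters_per_dimension)) {
        vox <- grow_cluster(lobes[ci], sizes[[d]][ci], used)
        used[vox] <- TRUE
        sgn <- sample(c(1, 1, 1, -1), 1)
        loading[vox, d] <- sgn * stats::runif(length(vox), 0.6, 1.0)
        cl[[ci]] <- list(lobe = lobes[ci], seed_voxel = vox[1],
                         voxels = vox, size = length(vox), sign = sgn)
      }
      spec[[d]] <- cl
    }
    list(loading = loading, spec = spec, used = used)
  }

  fac <- plant(seq_len(nd), used)

  # student group: relocate `group_effect` clusters per semantic dimension
  loading_student <- fac$loading
  spec_student <- fac$spec
  used2 <- fac$used
  n_shift <- min(group_effect, clusters_per_dimension)
  if (n_shift > 0) {
    for (d in seq_len(nd)) {
      if (identical(dimension_names[d], "word_length")) next
      for (ci in seq_len(n_shift)) {
        old <- spec_student[[d]][[ci]]
        loading_student[old$voxels, d] <- 0
        vox <- grow_cluster(old$lobe, old$size, used2)
        used2[vox] <- TRUE
        loading_student[vox, d] <- old$sign * stats::runif(length(vox), 0.6, 1.0)
        spec_student[[d]][[ci]] <- list(lobe = old$lobe, seed_voxel = vox[1],
                                        voxels = vox, size = length(vox),
                                        sign = old$sign)
      }
    }
  }

  structure(list(concept_scores = scores,
                 dimension_names = dimension_names,
                 loading_map = fac$loading,
                 loading_map_student = loading_student,
                 cluster_spec = fac$spec,
                 cluster_spec_student = spec_student,
                 noise_sd = noise_sd,
                 participant_sd = participant_sd,
                 group_effect = group_effect,
                 geometry = geometry,
                 concept_labels = concept_labels,
                 concept_categories = concept_categories,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Face-adjacent (6-connectivity) neighbors of a voxel index.
face_neighbors <- function(geometry, v) {
  g <- geometry$grid_shape
  ijk <- geometry$ijk[v, ]
  out <- integer(0)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      p <- ijk
      p[a] <- p[a] + s
      if (p[a] >= 1 && p[a] <= g[a]) {
        out <- c(out, ijk_to_index(geometry, matrix(p, ncol = 3)))
      }
    }
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d concepts x %d dimensions on %d voxels (seed %d)\n",
              nrow(x$concept_scores), ncol(x$concept_scores),
              x$geometry$n_voxels, x$seed))
  cat("dimensions:", paste(x$dimension_names, collapse = ", "), "\n")
  cat(sprintf("noise_sd = %.3g, participant_sd = %.3g, group_effect = %d\n",
              x$noise_sd, x$participant_sd, x$group_effect))
  invisible(x)
}
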