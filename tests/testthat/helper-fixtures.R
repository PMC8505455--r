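# Shared fixtures: all synthetic, generated in code at test time.

tiny_geometry <- function(shape = c(6, 6, 4)) make_geometry(shape)

# Small ground truth: 20 concepts, two semantic dimensions plus the
# word-length nuisance dimension, on a 144-voxel grid. Labels vary in
# length so the word-length dimension is well defined.
tiny_gt <- function(seed = 7, noise_sd = 0.1, ...) {
  labels <- paste0("c", seq_len(20), vapply(seq_len(20), function(i) {
    strrep("x", i %% 8)
  }, ""))
  sample_ground_truth(n_concepts = 20,
                      dimension_names = c("dimA", "dimB", "word_length"),
                      clusters_per_dimension = 2,
                      cluster_size_range = c(2, 4),
                      noise_sd = noise_sd,
                      geometry = tiny_geometry(),
                      concept_labels = labels,
                      seed = seed,
                      ...)
}

# Minimal activation dataset of pure Gaussian noise (no geometry needed for
# whole-brain decoding paths).
noise_dataset <- function(seed, n_concepts = 8, n_presentations = 4,
                          n_voxels = 30) {
  set.seed(seed)
  structure(list(participant_id = seed, group = "faculty",
                 psc = array(stats::rnorm(n_concepts * n_presentations * n_voxels),
                             c(n_concepts, n_presentations, n_voxels)),
                 concept_labels = paste0("c", seq_len(n_concepts)),
                 geometry = NULL),
            class = "activation_dataset")
}

# Hand-built group feature table: n_per_group participants per group, with
# a mean shift of +/- delta on the rows in signal_concepts (faculty up,
# students down).
make_group_table <- function(signal_concepts = integer(0), delta = 0,
                             n_concepts = 5, n_clusters = 2,
                             n_per_group = 4, seed = 1) {
  set.seed(seed)
  blk <- function(sgn) {
    m <- matrix(stats::rnorm(n_concepts * n_clusters), n_concepts, n_clusters)
    if (length(signal_concepts)) {
      m[signal_concepts, ] <- m[signal_concepts, ] + sgn * delta
    }
    m
  }
  feats <- c(lapply(seq_len(n_per_group), function(i) blk(1)),
             lapply(seq_len(n_per_group), function(i) blk(-1)))
  structure(list(features = feats,
                 group = rep(c("faculty", "student"), each = n_per_group),
                 concepts = paste0("c", seq_len(n_concepts))),
            class = "group_feature_table")
}

# Hand-built cluster map on a given geometry.
make_cluster_map <- function(vox_list, factors, geometry) {
  clusters <- mapply(function(v, f) {
    list(factor = f, voxels = v, size = length(v),
         centroid = colMeans(voxel_mm(geometry, v)),
         lobe = geometry$lobe[v[1]])
  }, vox_list, factors, SIMPLIFY = FALSE)
  structure(list(clusters = clusters, unassigned = integer(0),
                 connectivity = 6, geometry = geometry),
            class = "cluster_map")
}
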