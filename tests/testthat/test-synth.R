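test_that("geometry construction: octant partition, voxel volume, affine origin", {
  g <- make_geometry(c(4, 4, 4))
  expect_equal(g$n_voxels, 64)
  expect_setequal(unique(g$lobe),
                  c("frontal", "parietal", "temporal-fusiform", "occipital"))
  expect_true(all(table(g$lobe) > 0))
  expect_equal(g$voxel_volume_mm3, 58.59375)
  expect_equal(round(cluster_volume_mm3(2, g)), 117)

  g2 <- make_geometry(c(2, 2, 2), origin = c(10, 20, 30))
  expect_equal(unname(voxel_mm(g2, 1)[1, ]), c(10, 20, 30))

  expect_error(make_geometry(c(2, 2, 2), lobe_partition = rep("frontal", 8)),
               "parietal")
  expect_error(make_geometry(c(2, 2, 2), lobe_partition = rep("cerebellum", 8)),
               "unknown")
  expect_error(make_geometry(c(0, 2, 2)), "positive")
})

test_that("ground truth: determinism, z-scoring, cluster geometry by brute-force scan", {
  gt1 <- tiny_gt()
  gt2 <- tiny_gt()
  expect_identical(gt1$concept_scores, gt2$concept_scores)
  expect_identical(gt1$loading_map, gt2$loading_map)
  expect_identical(gt1$cluster_spec, gt2$cluster_spec)

  expect_equal(unname(colMeans(gt1$concept_scores)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(gt1$concept_scores, 2, sd)), rep(1, 3),
               tolerance = 1e-12)

  # exhaustive scan of the loading map: per dimension, the nonzero voxels
  # decompose into face-connected components within the declared size range
  for (d in seq_along(gt1$dimension_names)) {
    vox <- which(gt1$loading_map[, d] != 0)
    comps <- neurosem:::grid_components(vox, gt1$geometry, 6)
    expect_equal(length(comps), 2)
    expect_true(all(lengths(comps) >= 2 & lengths(comps) <= 4))
  }
  # planted clusters disjoint across dimensions
  expect_true(all(rowSums(gt1$loading_map != 0) <= 1))
  # word-length clusters only in the occipital partition
  wl <- which(gt1$loading_map[, "word_length"] != 0)
  expect_true(all(gt1$geometry$lobe[wl] == "occipital"))

  # capacity error names the lobe
  expect_error(sample_ground_truth(n_concepts = 5,
                                   dimension_names = c("a", "word_length"),
                                   clusters_per_dimension = 40,
                                   cluster_size_range = c(4, 4),
                                   geometry = tiny_geometry(),
                                   concept_labels = paste0("l", 1:5, strrep("y", 1:5)),
                                   seed = 2),
               "capacity")
  expect_error(sample_ground_truth(n_concepts = 1), "at least 2")
  expect_error(sample_ground_truth(n_concepts = 5, cluster_size_range = c(1, 3),
                                   geometry = tiny_geometry(),
                                   concept_labels = paste0("l", 1:5)),
               "minimum >= 2")
})

test_that("word-length scores track label character counts", {
  labels <- c("light", "acceleration", "torque", "dark matter plus extra")
  gt <- sample_ground_truth(n_concepts = 4,
                            dimension_names = c("dimA", "word_length"),
                            clusters_per_dimension = 2,
                            cluster_size_range = c(2, 3),
                            geometry = tiny_geometry(),
                            concept_labels = labels, seed = 1)
  expect_equal(order(gt$concept_scores[, "word_length"]), order(nchar(labels)))
})

test_that("participant simulation: zero-noise degeneracy and per-participant determinism", {
  gt <- tiny_gt(noise_sd = 0)
  d <- simulate_participant(gt, 1, 4, "faculty")
  expect_equal(d$psc[, 1, ], d$psc[, 2, ])
  expect_equal(d$psc[, 1, ], d$psc[, 4, ])

  st <- suppressMessages(voxel_stability(d$psc))
  incl <- which(rowSums(gt$loading_map != 0) > 0)
  expect_equal(unname(st[incl]), rep(1, length(incl)))
  expect_true(all(!is.finite(st[-incl])))   # flat noise voxels are sentinels

  d2 <- simulate_participant(gt, 1, 4, "faculty")
  expect_identical(d$psc, d2$psc)
  d3 <- simulate_participant(gt, 2, 4, "faculty")
  expect_false(identical(d$psc, d3$psc))

  expect_error(simulate_participant(gt, 1, 4, "postdoc"))
  expect_error(simulate_participant(gt, 1, 1), "at least 2")
})

test_that("with zero loadings the tensor is pure noise with near-zero stability", {
  gt <- sample_ground_truth(seed = 5, noise_sd = 0.5)
  gt$loading_map[] <- 0
  d <- simulate_participant(gt, 1, 6, "faculty")
  st <- voxel_stability(d$psc)          # 1152 voxels, Monte-Carlo null
  expect_true(all(is.finite(st)))
  expect_lt(abs(mean(st)), 0.02)
})

test_that("group effect relocates semantic clusters but not word-length clusters", {
  gt <- tiny_gt()
  expect_false(identical(gt$loading_map, gt$loading_map_student))
  expect_identical(gt$cluster_spec$word_length, gt$cluster_spec_student$word_length)
  for (dim in c("dimA", "dimB")) {
    expect_false(identical(gt$cluster_spec[[dim]][[1]]$voxels,
                           gt$cluster_spec_student[[dim]][[1]]$voxels))
    # relocation stays within the planted lobe
    expect_identical(gt$cluster_spec[[dim]][[1]]$lobe,
                     gt$cluster_spec_student[[dim]][[1]]$lobe)
  }
  # no group effect -> identical maps
  gt0 <- tiny_gt(group_effect = 0)
  expect_identical(gt0$loading_map, gt0$loading_map_student)
})

test_that("ratings: monotone noiseless map, boundary clipping, reproducible noise", {
  gt <- tiny_gt()
  r0 <- simulate_ratings(gt, c("dimA", "dimB"), n_raters = 1, rater_noise_sd = 0)
  expect_true(all(r0 >= 1 & r0 <= 7))
  for (d in c("dimA", "dimB")) {
    ord <- order(gt$concept_scores[, d])
    expect_true(all(diff(r0[ord, d]) >= 0))   # monotone in the true score
  }

  gt$concept_scores[1, "dimA"] <- 2.5          # at/beyond the +2 sd endpoint
  r1 <- simulate_ratings(gt, "dimA", n_raters = 3, rater_noise_sd = 0)
  expect_equal(unname(r1[1, "dimA"]), 7)

  ra <- simulate_ratings(gt, "dimA", n_raters = 6, rater_noise_sd = 1, seed = 99)
  rb <- simulate_ratings(gt, "dimA", n_raters = 6, rater_noise_sd = 1, seed = 99)
  expect_identical(unclass(ra), unclass(rb))

  # Pearson r against truth matches the direct product-moment formula
  x <- ra[, 1]; y <- gt$concept_scores[, "dimA"]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(cor(x, y)), r_direct, tolerance = 1e-12)

  expect_error(simulate_ratings(gt, "word_length"), "word_length")
  expect_error(simulate_ratings(gt, "dimA", n_raters = 0), "at least 1")
  expect_error(simulate_ratings(gt, "nope"), "subset")
})

test_that("cohort assembly: shapes, group labels, shared geometry, determinism", {
  gt <- tiny_gt()
  co <- simulate_cohort(gt, 2, 1, 3)
  expect_length(co, 3)
  expect_equal(vapply(co, function(d) d$group, ""),
               c("faculty", "faculty", "student"))
  expect_equal(dim(co[[1]]$psc), c(20, 3, 144))
  expect_identical(co[[2]]$geometry, co[[3]]$geometry)
  expect_equal(vapply(co, function(d) d$participant_id, 1L), 1:3)
  co2 <- simulate_cohort(gt, 2, 1, 3)
  expect_identical(co, co2)
  expect_error(simulate_cohort(gt, 0, 0), "at least one")
})

test_that("timecourse mode round-trips exactly through compute_psc", {
  gt <- tiny_gt()
  d <- simulate_participant(gt, 1, 2)
  tc <- simulate_timecourse(d)
  psc <- compute_psc(tc$series, tc$onsets, tc$baseline)
  expected <- t(vapply(seq_along(tc$onsets), function(tr) {
    d$psc[tc$events$concept[tr], tc$events$presentation[tr], ]
  }, numeric(dim(d$psc)[3])))
  expect_equal(unname(psc), unname(expected), tolerance = 1e-10)
})
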