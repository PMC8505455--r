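test_that("GNB training: hand-computed posteriors, mode at the mean, degenerate features", {
  # 1 feature, 2 classes with means 0 and 1 and pooled variance 2
  X <- matrix(c(-1, 1, 0, 2), 4, 1)
  y <- c("a", "a", "b", "b")
  m <- train_gnb(X, y)
  expect_equal(unname(m$means[, 1]), c(0, 1))
  expect_equal(unname(m$var), 2)
  lp <- predict(m, matrix(0.2, 1, 1))
  expect_equal(unname(lp[1, "a"] - lp[1, "b"]),
               dnorm(0.2, 0, sqrt(2), log = TRUE) -
                 dnorm(0.2, 1, sqrt(2), log = TRUE),
               tolerance = 1e-12)

  # a test vector equal to a class mean attains the maximum posterior
  set.seed(9)
  X2 <- matrix(rnorm(40), 20, 2)
  y2 <- rep(letters[1:5], each = 4)
  m2 <- train_gnb(X2, y2)
  for (k in 1:5) {
    expect_equal(unname(predict(m2, m2$means[k, , drop = FALSE], type = "class")),
                 m2$levels[k])
  }

  # constant feature is floored, no division error
  m3 <- train_gnb(cbind(X2, 7), y2)
  expect_true(all(is.finite(predict(m3, cbind(X2, 7)))))

  expect_error(train_gnb(X2, factor(y2, levels = c(letters[1:5], "z"))),
               "0 exemplars")
})

test_that("GNB posteriors equal brute-force Gaussian density computations", {
  set.seed(10)
  X <- matrix(rnorm(9 * 3), 9, 3)
  y <- rep(c("a", "b", "c"), each = 3)
  Xt <- matrix(rnorm(6 * 3), 6, 3)
  for (vtype in c("pooled", "per_class")) {
    m <- train_gnb(X, y, variance = vtype)
    post <- predict(m, Xt, type = "posterior")
    brute <- matrix(NA_real_, 6, 3)
    for (i in 1:6) {
      for (k in 1:3) {
        v <- if (vtype == "pooled") m$var else m$var[k, ]
        brute[i, k] <- prod(dnorm(Xt[i, ], m$means[k, ], sqrt(v))) / 3
      }
    }
    brute <- brute / rowSums(brute)
    expect_equal(unname(post), brute, tolerance = 1e-10)
  }
})

test_that("normalized rank accuracy: formula, tie averaging, monotone invariance, chance", {
  sc <- matrix(45:1, 1, 45, dimnames = list(NULL, paste0("c", 1:45)))
  expect_equal(rank_accuracy(sc, "c1")$mean, 1)
  expect_equal(rank_accuracy(sc, "c23")$mean, 0.5)   # (45 - 23) / 44
  expect_equal(rank_accuracy(sc, "c45")$mean, 0)

  sc2 <- matrix(c(1, 1, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(rank_accuracy(sc2, "a")$mean, (3 - 1.5) / 2)  # tied ranks averaged

  set.seed(11)
  raw <- matrix(rnorm(80), 10, 8, dimnames = list(NULL, letters[1:8]))
  labs <- sample(letters[1:8], 10, TRUE)
  expect_equal(rank_accuracy(exp(raw), labs)$per_item,
               rank_accuracy(raw, labs)$per_item)

  set.seed(12)
  n <- 2000
  scores <- matrix(rnorm(n * 45), n, 45, dimnames = list(NULL, paste0("c", 1:45)))
  labs2 <- sample(paste0("c", 1:45), n, TRUE)
  expect_lt(abs(rank_accuracy(scores, labs2)$mean - 0.5), 0.02)

  expect_error(rank_accuracy(sc, "nope"), "absent")
  expect_error(rank_accuracy(matrix(1, 1, 1, dimnames = list(NULL, "a")), "a"),
               "2 classes")
})

test_that("within-participant CV: fold count, separable ceiling, region exclusion, null", {
  gt <- tiny_gt(noise_sd = 0)
  d <- simulate_participant(gt, 1, 6)
  cv <- suppressWarnings(suppressMessages(within_participant_cv(d, n_features = 12)))
  expect_equal(ncol(cv$folds), choose(6, 2))
  expect_equal(cv$mean_accuracy, 1.0)

  cv2 <- suppressWarnings(suppressMessages(
    within_participant_cv(d, n_features = 12, exclude_region = "occipital",
                          details = TRUE)))
  occ <- which(d$geometry$lobe == "occipital")
  for (f in cv2$details) expect_length(intersect(f$selected_voxels, occ), 0)

  expect_error(within_participant_cv(simulate_participant(gt, 1, 2)),
               "at least 3")
  expect_error(within_participant_cv(d, exclude_region = "cerebellum"),
               "unknown region")

  # label-permuted data sits at chance (20 replicates)
  gtn <- tiny_gt(noise_sd = 0.3)
  accs <- vapply(1:20, function(r) {
    set.seed(2000 + r)
    dd <- simulate_participant(gtn, r, 4)
    for (p in 1:4) dd$psc[, p, ] <- dd$psc[sample(20), p, ]
    suppressWarnings(suppressMessages(within_participant_cv(
      dd, n_features = 12, fold_scheme = "disjoint")))$mean_accuracy
  }, 1.0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("cross-participant CV: clones, independent noise, fold protocol", {
  gt <- tiny_gt(noise_sd = 0.05)
  d <- simulate_participant(gt, 1, 4)
  cv <- suppressWarnings(suppressMessages(
    cross_participant_cv(list(d, d, d, d), n_features = 12)))
  expect_length(cv$fold_accuracy, 4)      # one fold per participant
  expect_equal(cv$mean_accuracy, 1.0)

  nul <- suppressWarnings(suppressMessages(
    cross_participant_cv(lapply(1:4, noise_dataset), n_features = 20)))
  expect_lt(abs(nul$mean_accuracy - 0.5), 0.1)

  expect_error(cross_participant_cv(list(d, d)), "at least 3")
  d2 <- d; d2$concept_labels <- rev(d2$concept_labels)
  expect_error(cross_participant_cv(list(d, d, d2)), "mismatched")
})

test_that("permutation test: extreme case, add-one bound", {
  gt <- tiny_gt(noise_sd = 0.1)
  d <- simulate_participant(gt, 1, 4)
  stat <- function(x) {
    suppressWarnings(suppressMessages(within_participant_cv(
      x, n_features = 12, fold_scheme = "disjoint")))$mean_accuracy
  }
  obs <- stat(d)
  pt <- permutation_test(obs, d, stat, n_permutations = 19, seed = 3)
  expect_true(all(pt$perm_stats < obs))   # strong signal beats every permutation
  expect_equal(pt$p_value, 1 / 20)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
  # reproducible given the seed
  pt2 <- permutation_test(obs, d, stat, n_permutations = 19, seed = 3)
  expect_identical(pt$perm_stats, pt2$perm_stats)
  expect_error(permutation_test(obs, d, stat, n_permutations = 0), "at least 1")
})

test_that("category-mean classification: separable planted contrast, noise null, bounds", {
  gt <- tiny_gt(noise_sd = 0.05)
  cats <- rep(c("classical", "post-classical"), each = 10)
  gt$concept_scores[, "dimA"] <- as.numeric(
    scale(ifelse(cats == "classical", 1, -1) + rnorm(20, 0, 0.05)))
  d <- simulate_participant(gt, 1, 4)
  res <- classify_category_means(d, cats)
  expect_equal(res$grand_mean, 1.0)
  expect_true(res$grand_mean >= 0 && res$grand_mean <= 1)

  # pure-noise data sit at chance over 20 replicates
  gtn <- tiny_gt(noise_sd = 0.3)
  gtn$loading_map[] <- 0
  accs <- vapply(1:20, function(r) {
    classify_category_means(simulate_participant(gtn, r, 4), cats)$grand_mean
  }, 1.0)
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  expect_error(classify_category_means(d, rep(c("a", "b", "c"), length.out = 20)),
               "two levels")
  expect_error(classify_category_means(d, c("a", rep("b", 19))), "fewer than 2")
})

test_that("fold artifacts are unaffected by held-out data (leakage guard)", {
  gt <- tiny_gt(noise_sd = 0.1)
  d <- simulate_participant(gt, 1, 4)
  cv <- suppressWarnings(suppressMessages(
    within_participant_cv(d, n_features = 12, details = TRUE)))
  d2 <- d
  tp <- cv$details[[1]]$test_presentations
  d2$psc[, tp, ] <- d2$psc[, tp, ] + 100   # corrupt fold 1's test data only
  cv2 <- suppressWarnings(suppressMessages(
    within_participant_cv(d2, n_features = 12, details = TRUE)))
  expect_identical(cv$details[[1]]$selected_voxels,
                   cv2$details[[1]]$selected_voxels)
  expect_identical(cv$details[[1]]$model, cv2$details[[1]]$model)
  # but the test-set accuracy of that fold does change
  expect_false(identical(cv$fold_accuracy[1], cv2$fold_accuracy[1]))
})
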