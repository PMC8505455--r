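test_that("principal-axis extraction matches eigen oracles and validates input", {
  # identity correlation: SMC priors all zero, all loadings zero
  expect_warning(sol <- principal_factor_analysis(diag(4), 2),
                 "positive eigenvalues")
  expect_equal(unname(sol$loadings), matrix(0, 4, 2))
  expect_equal(unname(sol$communalities), rep(0, 4))

  # 3 equicorrelated variables, 1 factor: eigen oracle on the reduced matrix
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  sol1 <- principal_factor_analysis(R, 1)
  smc <- 1 - 1 / diag(solve(R))
  red <- R; diag(red) <- smc
  ee <- eigen(red, symmetric = TRUE)
  oracle <- ee$vectors[, 1] * sqrt(ee$values[1])
  expect_equal(abs(unname(sol1$loadings[, 1])), abs(oracle), tolerance = 1e-10)

  # 6-variable toy with two planted factors vs an independently coded
  # principal-axis reference
  Lp <- cbind(c(.8, .7, .9, 0, 0, 0), c(0, 0, 0, .7, .8, .6))
  R2 <- Lp %*% t(Lp); diag(R2) <- 1
  sol2 <- principal_factor_analysis(R2, 2)
  pa_reference <- function(R, k) {
    h <- 1 - 1 / diag(solve(R))
    Rr <- R
    for (i in seq_len(nrow(R))) Rr[i, i] <- h[i]
    e <- eigen(Rr, symmetric = TRUE)
    sweep(e$vectors[, 1:k, drop = FALSE], 2, sqrt(e$values[1:k]), "*")
  }
  expect_equal(abs(unname(sol2$loadings)), abs(pa_reference(R2, 2)),
               tolerance = 1e-6)

  # variable order invariance up to bookkeeping
  p <- c(4, 1, 6, 2, 5, 3)
  solp <- principal_factor_analysis(R2[p, p], 2)
  expect_equal(abs(unname(solp$loadings)), abs(unname(sol2$loadings[p, ])),
               tolerance = 1e-8)

  expect_error(principal_factor_analysis(matrix(c(1, .5, .2, 1), 2), 1),
               "symmetric")
  expect_error(principal_factor_analysis(2 * diag(2), 1), "unit diagonal")
  expect_error(principal_factor_analysis(diag(3), 5), "between 1")
})

test_that("varimax rotation: fixed point, invariants, grid-search oracle", {
  # perfect simple structure is a fixed point up to permutation and sign
  L <- rbind(c(.9, 0), c(.8, 0), c(0, .7), c(0, .6))
  Lr <- varimax_rotate(L)
  same <- isTRUE(all.equal(abs(Lr), abs(L), tolerance = 1e-6)) ||
    isTRUE(all.equal(abs(Lr[, 2:1]), abs(L), tolerance = 1e-6))
  expect_true(same)

  # communalities preserved, criterion never decreased (property loop)
  set.seed(2)
  for (rep in 1:5) {
    L2 <- matrix(rnorm(18), 6, 3)
    L2r <- varimax_rotate(L2)
    expect_equal(rowSums(L2r^2), rowSums(L2^2), tolerance = 1e-8)
    expect_gte(neurosem:::varimax_criterion(L2r) -
                 neurosem:::varimax_criterion(L2), -1e-8)
    # sign convention: the largest-|loading| entry of each column is positive
    for (j in 1:3) expect_gte(L2r[which.max(abs(L2r[, j])), j], 0)
  }

  # two-factor rotation equals a 1e-4-rad grid search over the criterion
  set.seed(3)
  L3 <- matrix(rnorm(10), 5, 2)
  ours <- varimax_rotate(L3)
  crit_ours <- neurosem:::varimax_criterion(ours)
  thetas <- seq(0, pi / 2, by = 1e-4)
  crit_grid <- vapply(thetas, function(th) {
    G <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    neurosem:::varimax_criterion(L3 %*% G)
  }, 1.0)
  expect_gte(crit_ours, max(crit_grid) - 1e-6)

  # single factor passes through; non-finite input errors
  expect_equal(abs(varimax_rotate(matrix(c(-1, 2), 2, 1))), matrix(c(1, 2), 2, 1))
  expect_error(varimax_rotate(matrix(c(1, NA), 1)), "finite")
})

test_that("regression factor scores: recovery, closed-form check, centering", {
  set.seed(4)
  f <- rnorm(30)
  lam <- c(.9, .8, .7, .6)
  X <- outer(f, lam) + matrix(rnorm(120, 0, 1e-8), 30)
  R <- cor(X)
  sol <- suppressWarnings(principal_factor_analysis(R, 1))
  sc <- suppressMessages(factor_scores(X, sol$loadings, R))
  expect_gt(abs(cor(sc[, 1], f)), 0.9999)

  # 2-variable closed-form check: Z %*% R^-1 %*% L
  X2 <- matrix(c(1, 2, 3, 2, 1, 4), 3, 2)
  L2 <- matrix(c(0.5, 0.3), 2, 1)
  expected <- scale(X2) %*% solve(cor(X2)) %*% L2
  got <- factor_scores(X2, L2)
  expect_equal(unname(got), unname(expected), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(got))), 1e-10)

  # singular correlation: ridge fallback is reported and finite
  X3 <- cbind(X2, X2[, 1])
  expect_message(sc3 <- factor_scores(X3, matrix(c(.5, .3, .5), 3, 1)), "ridge")
  expect_true(all(is.finite(sc3)))
})

test_that("individual-level FA recovers planted structure per lobe", {
  gt <- tiny_gt(noise_sd = 0.02)
  d <- simulate_participant(gt, 1, 6)
  fa <- suppressWarnings(suppressMessages(
    individual_level_fa(d, n_per_lobe = 30, n_factors = 5)))
  expect_setequal(names(fa$lobes),
                  c("frontal", "parietal", "temporal-fusiform", "occipital"))
  expect_true(all(vapply(fa$lobes,
                         function(l) ncol(l$solution$loadings) <= 5, TRUE)))
  expect_true(all(vapply(fa$lobes, function(l) length(l$voxels) <= 30, TRUE)))

  # dimA is planted in frontal and parietal; a parietal factor must match it
  sc <- fa$lobes[["parietal"]]$solution$scores
  expect_gte(max(abs(cor(sc, gt$concept_scores[, "dimA"]))), 0.95)
  # the word-length dimension appears among the occipital factors
  sco <- fa$lobes[["occipital"]]$solution$scores
  expect_gte(max(abs(cor(sco, gt$concept_scores[, "word_length"]))), 0.95)
  # score columns are standardized
  expect_lt(max(abs(colMeans(sc))), 1e-10)
})

test_that("group-level FA: degenerate retention, thresholds, planted recovery", {
  set.seed(5)
  x <- rnorm(20)
  S <- matrix(rep(x, 6), 20, 6)
  sol <- suppressMessages(group_level_fa(S))
  expect_equal(ncol(sol$loadings), 1)

  expect_warning(empty <- suppressMessages(group_level_fa(S, variance_threshold = 100)),
                 "no factor")
  expect_equal(ncol(empty$loadings), 0)

  gt <- tiny_gt(noise_sd = 0.02)
  co <- lapply(1:3, function(i) simulate_participant(gt, i, 6))
  ind <- lapply(co, function(d) suppressWarnings(suppressMessages(
    individual_level_fa(d, n_per_lobe = 30, n_factors = 5))))
  gsol <- suppressMessages(group_level_fa(ind))
  m <- match_factors_to_truth(gsol, gt)
  # every planted non-nuisance dimension recovered at |r| >= 0.9; the
  # word-length nuisance dimension at least at the interpretability bar
  expect_true(all(abs(m$r[m$dimension != "word_length"]) >= 0.9))
  expect_gte(abs(m$r[m$dimension == "word_length"]), 0.7)

  # inconsistent concept sets error
  bad <- ind
  bad[[2]]$lobes[[1]]$solution$scores <-
    bad[[2]]$lobes[[1]]$solution$scores[1:10, , drop = FALSE]
  expect_error(suppressMessages(group_level_fa(bad)), "inconsistent")
})

test_that("voxel-factor assignment applies the absolute-loading threshold", {
  expect_identical(assign_voxels_to_factors(matrix(0.39, 1, 1)), NA_integer_)
  expect_identical(assign_voxels_to_factors(matrix(c(0.6, -0.7), 1)), 2L)
  expect_true(all(is.na(assign_voxels_to_factors(matrix(0.4, 3, 2)))))
  expect_identical(assign_voxels_to_factors(matrix(c(0.5, 0.41), 1)), 1L)
  expect_error(assign_voxels_to_factors(matrix(NA_real_, 1, 1)), "finite")
})

test_that("cluster extraction: adjacency rules, min size, centroids, determinism", {
  g <- make_geometry(c(4, 4, 4))
  a <- rep(NA_integer_, 64)
  a[c(1, 2)] <- 1L                         # face-adjacent along x
  cm <- extract_clusters(a, g)
  expect_length(cm$clusters, 1)
  expect_equal(cm$clusters[[1]]$size, 2)
  expect_equal(round(cluster_volume_mm3(cm$clusters[[1]], g)), 117)
  expect_equal(cm$clusters[[1]]$centroid, colMeans(voxel_mm(g, 1:2)))

  a2 <- rep(NA_integer_, 64); a2[10] <- 1L # isolated voxel
  cm2 <- extract_clusters(a2, g)
  expect_length(cm2$clusters, 0)
  expect_equal(cm2$unassigned, 10)

  # corner-touching voxels (1,1,1) and (2,2,2): split under 6-connectivity,
  # joined under 26-connectivity
  a3 <- rep(NA_integer_, 64); a3[c(1, 22)] <- 1L
  expect_length(extract_clusters(a3, g, connectivity = 6)$clusters, 0)
  expect_length(extract_clusters(a3, g, connectivity = 26)$clusters, 1)

  # two factors, idempotent and deterministic
  a4 <- rep(NA_integer_, 64); a4[1:3] <- 1L; a4[c(33, 37)] <- 2L
  expect_identical(extract_clusters(a4, g), extract_clusters(a4, g))
  expect_error(extract_clusters(a4, g, connectivity = 18), "6 or 26")
})

test_that("secondary FA: residual recovery, noise rejection, edge cases", {
  set.seed(6)
  f5 <- rnorm(45)
  S <- sapply(1:5, function(i) f5 * runif(1, .8, 1) + rnorm(45, 0, 0.1))
  sol <- suppressMessages(secondary_fa(S))
  expect_gte(max(abs(cor(sol$scores, f5))), 0.9)

  # pure-noise residuals: no factor reaches the retention threshold
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    N <- matrix(rnorm(45 * 5), 45, 5)
    soln <- suppressWarnings(suppressMessages(secondary_fa(N)))
    hits <- hits + as.integer(ncol(soln$loadings) > 0)
  }
  expect_lte(hits, 2)

  one <- secondary_fa(S[, 1, drop = FALSE])
  expect_equal(ncol(one$loadings), 1)
  expect_equal(abs(cor(one$scores[, 1], S[, 1])), 1, tolerance = 1e-12)

  z <- secondary_fa(matrix(0, 30, 0))
  expect_equal(ncol(z$loadings), 0)
})

test_that("factor alignment: identity, permutation recovery, exhaustive matching oracle", {
  set.seed(7)
  S1 <- matrix(rnorm(80), 20, 4)
  al <- align_factors(list(S1, S1))
  expect_equal(al[[2]]$ref_factor, al[[2]]$factor)
  expect_equal(al[[2]]$r, rep(1, 4), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2); signs <- c(1, -1, 1, -1)
  S2 <- sweep(S1[, perm], 2, signs, "*")
  al2 <- align_factors(list(S1, S2))[[2]]
  got <- al2[order(al2$factor), ]
  expect_equal(got$ref_factor, perm)
  expect_equal(got$sign, signs)

  # greedy matching equals exhaustive search over all 4! permutations here
  C <- abs(cor(S1, S2))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  sums <- apply(perms, 1, function(pp) sum(C[cbind(pp, 1:4)]))
  bestp <- perms[which.max(sums), ]
  expect_equal(al2$ref_factor[order(al2$factor)], unname(bestp))

  # unmatched factors are listed
  al3 <- align_factors(list(S1[, 1:2], S2))
  expect_length(attr(al3, "unmatched")[[2]], 2)
})

test_that("score-rating correlations: affine invariance, extremes oracle, null p-values", {
  set.seed(8)
  sc <- matrix(rnorm(45), 45, 1, dimnames = list(NULL, "d"))
  rat <- sc * 0.5 + 3
  colnames(rat) <- "d"
  out <- correlate_scores_with_ratings(sc, rat)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 45)

  # extremes selection equals a brute-force sort (top 5 + bottom 5)
  noisy <- rat + matrix(rnorm(45, 0, 0.3), 45)
  colnames(noisy) <- "d"
  ext <- correlate_scores_with_ratings(sc, noisy, "extremes", extremes_k = 10)
  ord <- order(sc[, 1])
  pick <- c(ord[1:5], ord[41:45])
  expect_equal(ext$n, 10)
  expect_equal(ext$r, cor(sc[pick, 1], noisy[pick, 1]), tolerance = 1e-12)

  expect_error(correlate_scores_with_ratings(
    sc, matrix(3, 45, 1, dimnames = list(NULL, "d"))), "undefined")

  # under the null, p-values are uniform (KS at alpha = 0.01)
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    y <- matrix(runif(45, 1, 7), 45, 1, dimnames = list(NULL, "d"))
    correlate_scores_with_ratings(sc, y)$p
  }, 1.0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
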