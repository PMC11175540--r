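test_that("SI matrix concatenates coils, orders columns by time and centers rows", {
  acq <- planted_acquisition(24)
  sm <- build_si_matrix(acq$kdata)
  expect_equal(dim(sm$data), c(128 * 8, 24))
  expect_equal(max(abs(rowMeans(sm$data))), 0, tolerance = 1e-10)
  sm_rss <- build_si_matrix(acq$kdata, coil_combine = "rss")
  expect_equal(dim(sm_rss$data), c(128, 24))

  # static noiseless phantom: after centering the matrix is exactly zero
  sp <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 0,
                     noise_sigma = 0)
  traj <- generate_trajectory(3, 2, 16, ndim = 2, include_si = TRUE,
                              tr = 0.01)
  kd <- simulate_acquisition(sp, traj, make_coil_maps(48, 2, 1), seed = 1)
  expect_equal(dim(build_si_matrix(kd)$data), c(16, 3))
  expect_lt(max(abs(build_si_matrix(kd)$data)), 1e-9)

  kd$si_projections <- NULL
  expect_error(build_si_matrix(kd), "no SI projections")
})

test_that("PCA step matches a singular-value-decomposition oracle", {
  acq <- planted_acquisition(40)
  X <- build_si_matrix(acq$kdata)$data
  pc <- simbar:::pca_scores(X, n_components = 3)
  sv <- svd(X, nu = 3, nv = 0)
  oracle <- t(Re(Conj(t(sv$u)) %*% X))
  # scores match the SVD projection up to per-component sign
  for (j in 1:3) {
    expect_lt(min(max(abs(pc$scores[, j] - oracle[, j])),
                  max(abs(pc$scores[, j] + oracle[, j]))), 1e-8)
  }
})

test_that("selection minimizes the most-populated-cluster centroid distance
           and matches a brute-force oracle", {
  # planted 2D Gaussians with very unequal populations
  set.seed(31)
  ctrs <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), ncol = 2, byrow = TRUE)
  sizes <- c(90, 60, 30, 20)
  pts <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(2 * sizes[i], sd = 0.4), ncol = 2), 2,
          ctrs[i, ], `+`)))
  a <- cluster_with_selection(pts, k_range = c(2, 6), seed = 7)
  # independent brute-force loop: fresh k-means per k, explicit score,
  # plateau resolved to the largest k (the package's stated rule)
  sc <- vapply(2:6, function(k) {
    km <- simbar:::run_kmeans(pts, k, 7)
    big <- which.max(km$size)
    P <- pts[km$cluster == big, , drop = FALSE]
    mean(sqrt(rowSums(sweep(P, 2, km$centers[big, ])^2)))
  }, numeric(1))
  k_oracle <- (2:6)[max(which(sc <= min(sc) * (1 + 1e-6)))]
  expect_equal(a$k_selected, k_oracle)
  expect_equal(unname(a$scores_by_k), sc, tolerance = 1e-12)
  km_oracle <- simbar:::run_kmeans(pts, k_oracle, 7)
  expect_equal(a$labels, km_oracle$cluster)
})

test_that("a zero-spread most-populated cluster wins the selection", {
  # synthetic score sets: at k = 3 the largest cluster collapses onto its
  # centroid exactly
  set.seed(5)
  pts <- rbind(matrix(0, 50, 2),
               matrix(rnorm(40, sd = 0.3), 20, 2) + 5,
               matrix(rnorm(20, sd = 0.3), 10, 2) - 5)
  a <- cluster_with_selection(pts, k_range = c(2, 4), seed = 3)
  expect_equal(unname(a$scores_by_k[a$k_selected - 1]), 0, tolerance = 1e-12)
})

test_that("labels partition interleaves and populations count readouts", {
  acq <- planted_acquisition(120)
  a <- cluster_with_selection(build_si_matrix(acq$kdata), k_range = c(2, 4),
                              seed = 9, readouts_per_interleave = 4)
  expect_equal(length(a$labels), 120)
  expect_setequal(unique(a$labels), seq_len(a$k_selected))
  expect_equal(sum(a$populations), 120 * 4)
  expect_equal(a$rank_order[1],
               which.max(a$populations))
  expect_equal(sort(a$populations, decreasing = TRUE),
               a$populations[a$rank_order])
})

test_that("imaging readouts inherit interleave labels; SI readouts excluded", {
  traj <- generate_trajectory(3, 22, 2, ndim = 3, include_si = TRUE,
                              tr = 0.003)
  a <- structure(list(labels = c(1L, 1L, 2L), k_selected = 2L,
                      populations = c(44L, 22L), rank_order = c(1L, 2L),
                      centroids = NULL, seed = 1, degenerate = FALSE),
                 class = "cluster_assignment")
  subs <- assign_readouts(a, traj, n_select = 2)
  expect_equal(length(subs[[1]]), 42)  # 2 interleaves x 21 imaging readouts
  expect_equal(length(subs[[2]]), 21)
  expect_false(any(traj$is_si[unlist(subs)]))
  expect_error(assign_readouts(a, traj, n_select = 3), "n_select")
  # default n_select is 4 (the reconstruction's cluster count)
  expect_equal(formals(assign_readouts)$n_select, 4)
})

test_that("clustering is invariant under interleave permutation (ARI = 1)", {
  skip_if_not_installed("mclust")
  acq <- planted_acquisition(120)
  sm <- build_si_matrix(acq$kdata)
  a1 <- cluster_with_selection(sm, k_range = c(2, 4), seed = 9)
  perm <- sample(120)
  sm2 <- sm
  sm2$data <- sm$data[, perm]
  sm2$data <- sm2$data - rowMeans(sm2$data)
  a2 <- cluster_with_selection(sm2, k_range = c(2, 4), seed = 9)
  expect_equal(a2$k_selected, a1$k_selected)
  expect_equal(mclust::adjustedRandIndex(a1$labels[perm], a2$labels), 1)
})

test_that("degenerate all-identical SI data returns k_min with a warning", {
  pts <- matrix(1, 30, 2)
  expect_warning(a <- cluster_with_selection(pts, k_range = c(2, 4),
                                             seed = 1),
                 "degenerate")
  expect_equal(a$k_selected, 2)
  expect_true(a$degenerate)
  expect_error(cluster_with_selection(matrix(rnorm(20), 10, 2),
                                      k_range = c(2, 12), seed = 1),
               "more SI readouts")
  expect_error(cluster_with_selection(matrix(rnorm(20), 10, 2),
                                      k_range = c(1, 3), seed = 1),
               "k_min")
})

test_that("default search range is the whole-heart protocol's 10 to 14", {
  expect_equal(eval(formals(cluster_with_selection)$k_range), c(10, 14))
})
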