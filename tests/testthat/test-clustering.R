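blob_points <- function(centers, per = 5, sd = 0.05, seed = 1) {
  set.seed(seed)
  pts <- unlist(lapply(centers, function(c0) c0 + rnorm(per, sd = sd)))
  matrix(pts, ncol = 1)
}

test_that("similarity matrix: closed forms and bandwidth policies", {
  pts <- matrix(c(0, 1, 1), ncol = 1)
  G <- similarity_matrix(pts, sigma = 2)
  expect_equal(unname(diag(G$S)), rep(1, 3))
  expect_equal(G$S, t(G$S))
  expect_equal(G$S[2, 3], 1)  # identical points

  # ||x_i - x_j||^2 = 2 sigma^2  =>  S_ij = exp(-1)
  G2 <- similarity_matrix(matrix(c(0, 2), ncol = 1), sigma = sqrt(2))
  expect_equal(G2$S[1, 2], exp(-1), tolerance = 1e-15)

  # median-pairwise policy: distances {3, 4, 1} have median 3
  G3 <- similarity_matrix(matrix(c(0, 3, 4), ncol = 1), sigma = "median")
  expect_equal(G3$sigma, 3)
  expect_equal(G3$S[1, 2], exp(-9 / 18), tolerance = 1e-15)

  # auto policy: median of (min(3, m-1))-th nearest-neighbour distances;
  # for (0, 3, 4) the 2nd-NN distances are (4, 3, 4), median 4
  G4 <- similarity_matrix(matrix(c(0, 3, 4), ncol = 1), sigma = "auto")
  expect_equal(G4$sigma, 4)

  expect_error(similarity_matrix(matrix(c(1, 1, 1), ncol = 1), sigma = "auto"),
               class = "mcdm_degenerate_points_error")
  expect_error(similarity_matrix(matrix(1:4, 2), sigma = -1),
               class = "mcdm_parameter_error")
})

test_that("Laplacian: zero row sums, PSD, diagonal-convention invariance", {
  pts <- blob_points(c(0, 5), per = 4, seed = 2)
  G <- similarity_matrix(pts, sigma = 1)
  LP <- laplacian(G)
  expect_true(max(abs(rowSums(LP$L))) <= 1e-10)
  ev <- eigen(LP$L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8))
  expect_lt(min(abs(ev)), 1e-8)

  # zeroing the diagonal of S changes D and S equally: L is unchanged
  G0 <- G
  diag(G0$S) <- 0
  expect_equal(laplacian(G0)$L, LP$L, tolerance = 1e-14)

  # 2-point closed form
  G2 <- similarity_matrix(matrix(c(0, 1), ncol = 1), sigma = 1)
  s <- G2$S[1, 2]
  L2 <- laplacian(G2)$L
  expect_equal(unname(L2), matrix(c(s, -s, -s, s), 2), tolerance = 1e-15)
  expect_equal(sort(eigen(L2, symmetric = TRUE)$values), c(0, 2 * s),
               tolerance = 1e-12)
})

test_that("spectral embedding: null space, component counting, residuals", {
  pts <- blob_points(c(0, 50), per = 4, sd = 0.01, seed = 3)
  G <- similarity_matrix(pts, sigma = 0.05)
  LP <- laplacian(G)

  E1 <- spectral_embedding(LP, 1)
  expect_equal(E1$eigenvalues[1], 0, tolerance = 1e-8)

  E <- spectral_embedding(LP, 4)
  expect_true(all(diff(E$eigenvalues) >= -1e-12))
  expect_equal(crossprod(E$U), diag(4), tolerance = 1e-8)
  # two far blobs with tiny sigma: exactly 2 near-zero eigenvalues
  all_ev <- spectral_embedding(LP, nrow(pts))$eigenvalues
  expect_identical(sum(abs(all_ev) <= 1e-8), 2L)

  # eigenpair residuals: L u = lambda u for every returned pair
  pts2 <- matrix(c(0, 1, 3), ncol = 1)
  LP2 <- laplacian(similarity_matrix(pts2, sigma = 1))
  E2 <- spectral_embedding(LP2, 3)
  for (j in 1:3) {
    expect_lt(max(abs(LP2$L %*% E2$U[, j] - E2$eigenvalues[j] * E2$U[, j])),
              1e-10)
  }
  # deterministic sign: largest-magnitude entry positive
  for (j in 1:3) {
    expect_gt(E2$U[which.max(abs(E2$U[, j])), j], 0)
  }
  expect_error(spectral_embedding(LP2, 4), class = "mcdm_parameter_error")
})

test_that("initial centers transfer the embedded partition to the original space", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  G <- similarity_matrix(pts, sigma = 1)
  E <- spectral_embedding(laplacian(G), 2)
  C <- initial_centers(pts, E, 2)
  expect_equal(sort(C[, 1]), c(0.05, 10.05))

  # k = 1: the global mean
  E1 <- spectral_embedding(laplacian(G), 1)
  expect_equal(initial_centers(pts, E1, 1)[1, 1], mean(pts))

  # k = m: every point its own center
  Em <- spectral_embedding(laplacian(G), 4)
  Cm <- initial_centers(pts, Em, 4)
  expect_equal(sort(Cm[, 1]), sort(pts[, 1]))
})

test_that("Lloyd iterations: fixed points, oracle bipartition, bookkeeping", {
  pts <- matrix(c(1, 2, 6), ncol = 1)
  g1 <- lloyd(pts, matrix(0, 1, 1))
  expect_equal(g1$centers[1, 1], 3)
  expect_equal(g1$inertia, sum((pts - 3)^2))
  expect_identical(g1$iterations, 1L)
  expect_true(g1$converged)

  pts2 <- matrix(c(0, 0.1, 0.2, 10, 10.1), ncol = 1)
  g2 <- lloyd(pts2, matrix(c(0, 9), ncol = 1))
  oracle <- oracle_best_2partition(pts2)
  expect_equal(g2$inertia, oracle$sse, tolerance = 1e-12)
  expect_identical(unname(g2$labels), oracle$labels)
  expect_equal(sort(g2$centers[, 1]), c(0.1, 10.05))

  # points already at their centers: immediate convergence, zero inertia
  pts3 <- matrix(c(0, 5, 9), ncol = 1)
  g3 <- lloyd(pts3, pts3)
  expect_identical(g3$iterations, 1L)
  expect_equal(g3$inertia, 0)

  # converged centers are the means of their members
  for (j in unique(g2$labels)) {
    members <- pts2[g2$labels == j, , drop = FALSE]
    expect_lt(max(abs(g2$centers[j + 1, ] - colMeans(members))), 1e-9)
  }
  # inertia trace never increases
  expect_true(all(diff(g2$inertia_history) <= 1e-12))

  # iteration budget exhausts gracefully
  g4 <- lloyd(pts2, matrix(c(0.15, 0.25), ncol = 1), max_iter = 1)
  expect_false(g4$converged)
})

test_that("empty clusters are reseeded deterministically", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  # both starting centers far right: one cluster starts empty
  g <- lloyd(pts, matrix(c(100, 101), ncol = 1))
  expect_identical(sort(unique(unname(g$labels))), c(0L, 1L))
  expect_equal(sort(g$centers[, 1]), c(0.05, 10.05))
})

test_that("graph-seeded k-means recovers separated blobs and is bit-stable", {
  gen <- generate_clustered_scores(
    synthetic_spec(m = 30, k_true = 6, noise_sd = 0.01, seed = 5))
  gr <- cluster_graph_kmeans(gen$scores, 6)
  expect_equal(vmeasure(gr$labels, gen$labels), 1)

  runs <- lapply(1:20, function(i) cluster_graph_kmeans(gen$scores, 6)$labels)
  expect_true(all(vapply(runs, identical, logical(1), y = runs[[1]])))

  expect_error(cluster_graph_kmeans(gen$scores, 31),
               class = "mcdm_validation_error")
})

test_that("baseline initializations are seeded and cover blobs", {
  pts <- blob_points(c(0, 20), per = 5, sd = 0.1, seed = 9)
  a <- baseline_init(pts, 3, "random", seed = 42)
  b <- baseline_init(pts, 3, "random", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, baseline_init(pts, 3, "random", seed = 43)))

  allp <- baseline_init(pts, nrow(pts), "random", seed = 1)
  expect_equal(sort(allp[, 1]), sort(pts[, 1]))

  # k-means++ separates dominant blobs for every seed
  hits <- vapply(1:50, function(s) {
    C <- baseline_init(pts, 2, "kmeanspp", seed = s)
    length(unique(C[, 1] > 10)) == 2
  }, logical(1))
  expect_true(all(hits))

  ff <- baseline_init(pts, 2, "farthest_first", seed = 7)
  expect_identical(length(unique(ff[, 1] > 10)), 2L)

  expect_error(baseline_init(pts, 2, "quantum"),
               class = "mcdm_unknown_method_error")
})
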