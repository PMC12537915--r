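test_that("weighted sum and product: selectors, constants, closed forms", {
  N <- as_norm(matrix(0.7, 3, 2))
  w <- new_test_weights(c(0.5, 0.5))
  expect_equal(unname(weighted_sum(N, w)), rep(0.7, 3))
  expect_equal(unname(weighted_product(N, w)), rep(0.7, 3))

  N2 <- as_norm(cbind(c(0.2, 0.9), c(0.8, 0.1)))
  expect_equal(unname(weighted_sum(N2, new_test_weights(c(1, 0)))),
               c(0.2, 0.9))
  expect_equal(unname(weighted_product(N2, new_test_weights(c(1, 0)))),
               c(0.2, 0.9), tolerance = 1e-15)

  expect_equal(unname(weighted_sum(as_norm(matrix(c(0.2, 0.8), 2, 2, byrow = TRUE)),
                                   new_test_weights(c(0.25, 0.75)))[1]), 0.65)
  expect_equal(unname(weighted_product(as_norm(matrix(c(0.25, 0.64), 2, 2, byrow = TRUE)),
                                       new_test_weights(c(0.5, 0.5)))[1]), 0.4,
               tolerance = 1e-15)

  expect_error(weighted_product(as_norm(cbind(c(0, 0.5), c(0.5, 0.5))),
                                new_test_weights(c(0.5, 0.5))),
               class = "mcdm_nonpositive_value_error")
  expect_error(weighted_sum(N2, new_test_weights(c(1, 0, 0))),
               class = "mcdm_shape_error")
})

test_that("WASPAS: endpoint identities, midpoint, monotonicity, AM-GM", {
  N <- rand_norm_matrix(6, 4, seed = 8)
  w <- new_test_weights(c(0.1, 0.2, 0.3, 0.4))
  st1 <- waspas_score(N, w, lambda = 1)
  st0 <- waspas_score(N, w, lambda = 0)
  expect_equal(st1$WQ, st1$WS, tolerance = 1e-15)
  expect_equal(st0$WQ, st0$WP, tolerance = 1e-15)
  st5 <- waspas_score(N, w, lambda = 0.5)
  expect_equal(st5$WQ, (st5$WS + st5$WP) / 2, tolerance = 1e-15)
  expect_error(waspas_score(N, w, lambda = 1.5), class = "mcdm_parameter_error")

  # AM-GM: WP <= WQ <= WS, so WQ is non-decreasing in lambda
  for (seed in 1:5) {
    Ns <- rand_norm_matrix(8, 3, seed = 200 + seed)
    ws <- new_test_weights(c(0.2, 0.3, 0.5))
    st <- waspas_score(Ns, ws)
    expect_true(all(st$WP <= st$WS + 1e-15))
    expect_true(all(st$WQ >= st$WP - 1e-15 & st$WQ <= st$WS + 1e-15))
    lams <- seq(0, 1, 0.25)
    wq <- sapply(lams, function(l) waspas_score(Ns, ws, l)$WQ)
    expect_true(all(diff(t(wq)) >= -1e-15))
  }

  # raising one normalized cell never lowers that alternative's WQ
  Nup <- rand_norm_matrix(5, 3, seed = 77)
  wv <- new_test_weights(c(0.4, 0.3, 0.3))
  base <- waspas_score(Nup, wv)
  V2 <- Nup$values; V2[2, 1] <- min(0.99, V2[2, 1] + 0.1)
  bumped <- waspas_score(as_norm(V2), wv)
  id <- rownames(Nup$values)[2]
  expect_gte(bumped$WQ[bumped$alternative == id],
             base$WQ[base$alternative == id])
})

test_that("rank_alternatives uses competition ranking with id tiebreak", {
  r <- rank_alternatives(c(a = 0.3, b = 0.9, c = 0.5))
  expect_identical(unname(as.integer(r)), c(3L, 1L, 2L))
  rt <- rank_alternatives(c(a = 0.5, b = 0.5))
  expect_identical(unname(as.integer(rt)), c(1L, 1L))
  rl <- rank_alternatives(c(a = 0.2, b = 0.8), higher_is_better = FALSE)
  expect_identical(unname(as.integer(rl)), c(1L, 2L))
  expect_error(rank_alternatives(c(1, NA)), class = "mcdm_validation_error")
})

test_that("published score columns reproduce the published ranks exactly", {
  t1 <- load_fixture("table1_scores")
  for (yr in c("2010", "2020")) {
    r <- rank_alternatives(stats::setNames(t1[[paste0("score_", yr)]],
                                           t1$country))
    expect_identical(unname(as.integer(r)), t1[[paste0("rank_", yr)]],
                     info = yr)
  }
})

test_that("TOPSIS: poles, oracle agreement, degeneracy", {
  # first alternative attains every column max: it IS the ideal point
  V <- rbind(c(0.9, 0.8, 0.9), c(0.1, 0.2, 0.3), c(0.5, 0.2, 0.4))
  ts <- topsis_score(as_norm(V), new_test_weights(c(0.3, 0.3, 0.4)))
  expect_equal(unname(ts$closeness[1]), 1)
  expect_equal(unname(ts$closeness[2]), 0)
  expect_identical(unname(as.integer(ts$ranks)), c(1L, 3L, 2L))

  N <- rand_norm_matrix(4, 3, seed = 12)
  w <- c(0.2, 0.5, 0.3)
  ts2 <- topsis_score(N, new_test_weights(w))
  expect_equal(unname(ts2$closeness), oracle_topsis(N$values, w),
               tolerance = 1e-12)

  expect_error(topsis_score(as_norm(matrix(0.4, 3, 2)),
                            new_test_weights(c(0.5, 0.5))),
               class = "mcdm_degenerate_alternatives_error")
})

test_that("VIKOR: ideal alternative, symmetry, oracle agreement", {
  V <- rbind(c(0.9, 0.8), c(0.4, 0.3), c(0.2, 0.6))
  vk <- vikor_score(as_norm(V), new_test_weights(c(0.5, 0.5)))
  expect_equal(unname(vk$S[1]), 0)
  expect_equal(unname(vk$R[1]), 0)
  expect_equal(unname(vk$Q[1]), 0)
  expect_identical(unname(as.integer(vk$ranks))[1], 1L)

  # two symmetric profiles: Q = 0 and 1
  V2 <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  vk2 <- vikor_score(as_norm(V2), new_test_weights(c(0.7, 0.3)))
  expect_equal(sort(unname(vk2$Q)), c(0, 1))

  N <- rand_norm_matrix(4, 3, seed = 13)
  w <- c(0.3, 0.4, 0.3)
  vk3 <- vikor_score(N, new_test_weights(w), v = 0.5)
  expect_equal(unname(vk3$Q), oracle_vikor(N$values, w, 0.5), tolerance = 1e-12)

  expect_error(vikor_score(as_norm(cbind(c(0.5, 0.5), c(0.1, 0.9))),
                           new_test_weights(c(0.5, 0.5))),
               class = "mcdm_degenerate_column_error")
})

test_that("every aggregator emits a complete ranking of 1..m", {
  N <- rand_norm_matrix(9, 4, seed = 3)
  w <- new_test_weights(c(0.25, 0.25, 0.25, 0.25))
  for (method in c("waspas", "topsis", "vikor")) {
    agg <- aggregate_scores(N, w, method)
    expect_identical(sort(unname(as.integer(agg$ranks))), 1:9, info = method)
  }
  expect_error(aggregate_scores(N, w, "borda"),
               class = "mcdm_unknown_method_error")
})
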