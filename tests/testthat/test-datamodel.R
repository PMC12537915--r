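test_that("decision_matrix validates shape, ids and finiteness", {
  V <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  X <- decision_matrix(V)
  expect_s3_class(X, "decision_matrix")
  expect_identical(dim(X), c(3L, 2L))
  expect_identical(unname(X$directions), c("benefit", "benefit"))

  expect_error(decision_matrix(matrix(0, 1, 2, dimnames = list("a", c("x", "y")))),
               class = "mcdm_validation_error")
  Vdup <- V; rownames(Vdup) <- c("a", "a", "c")
  expect_error(decision_matrix(Vdup), class = "mcdm_duplicate_id_error")
  Vna <- V; Vna[2, 1] <- NA
  expect_error(decision_matrix(Vna), class = "mcdm_nonfinite_error")
  expect_error(decision_matrix(V, directions = c(x = "benefit")),
               class = "mcdm_missing_direction_error")
  expect_error(decision_matrix(V, directions = c(x = "up", y = "cost")),
               class = "mcdm_direction_value_error")
})

test_that("read_decision_matrix parses CSVs and rejects malformed input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "zeros.csv")
  writeLines(c("alt,c1,c2", "a,0,0", "b,0,0", "c,0,0"), p)
  X <- read_decision_matrix(p)
  expect_identical(dim(X), c(3L, 2L))
  expect_true(all(X$values == 0))

  p2 <- file.path(dir, "dup.csv")
  writeLines(c("alt,c1", "AG,1", "AG,2", "BB,3"), p2)
  expect_error(read_decision_matrix(p2), class = "mcdm_duplicate_id_error")

  p3 <- file.path(dir, "text.csv")
  writeLines(c("alt,c1", "a,1", "b,oops", "c,3"), p3)
  expect_error(read_decision_matrix(p3), class = "mcdm_nonnumeric_error")

  expect_error(read_decision_matrix(file.path(dir, "nope.csv")),
               class = "mcdm_missing_file_error")

  # directions sidecar
  ds <- file.path(dir, "dirs.csv")
  writeLines(c("criterion_id,direction", "c1,cost", "c2,benefit"), ds)
  Xd <- read_decision_matrix(p, directions = ds)
  expect_identical(unname(Xd$directions), c("cost", "benefit"))
})

test_that("decision matrix CSV round-trips exactly", {
  dir <- withr::local_tempdir()
  set.seed(42)
  V <- matrix(rnorm(12) * 10^sample(-3:3, 12, TRUE), 4, 3,
              dimnames = list(paste0("alt", 1:4), paste0("c", 1:3)))
  X <- decision_matrix(V, directions = c(c1 = "cost", c2 = "benefit", c3 = "benefit"))
  p <- file.path(dir, "dm.csv"); pd <- file.path(dir, "dirs.csv")
  write_decision_matrix(X, p, directions_path = pd)
  X2 <- read_decision_matrix(p, directions = pd)
  expect_identical(X2$values, X$values)
  expect_identical(X2$directions, X$directions)
})

test_that("packaged fixtures match the published tables", {
  t1 <- load_fixture("table1_scores")
  expect_identical(nrow(t1), 35L)
  expect_equal(t1$score_2010[t1$country == "AG"], 0.5085)
  expect_equal(t1[t1$country == "US", c("score_2020", "rank_2020")],
               data.frame(score_2020 = 0.6161, rank_2020 = 1L,
                          row.names = which(t1$country == "US")))
  expect_equal(unname(unlist(t1[t1$country == "VC", c("score_2010", "rank_2010")])),
               c(0.7107, 1))

  t3 <- load_fixture("table3_norm_ranks")
  expect_equal(unname(unlist(t3[t3$country == "VC", -1])), c(1, 1, 1, 3, 7, 5))
  t5 <- load_fixture("table5_agg_ranks")
  expect_equal(unname(unlist(t5[t5$country == "BB", -1])), c(6, 3, 1, 2, 2, 1))
  t2 <- load_fixture("table2_groups")
  expect_identical(nrow(t2), 35L)
  expect_true(all(t2$group_2010 %in% 0:5) && all(t2$group_2020 %in% 0:5))

  expect_error(load_fixture("table99"), class = "mcdm_unknown_fixture_error")
})

test_that("fixture integrity: 35 rows, ranks in 1..35, frozen checksums", {
  rank_fixtures <- c("table3_norm_ranks", "table4_weight_ranks", "table5_agg_ranks")
  for (nm in rank_fixtures) {
    fx <- load_fixture(nm)
    expect_identical(nrow(fx), 35L)
    for (col in names(fx)[-1]) {
      expect_true(all(fx[[col]] %in% 1:35), info = paste(nm, col))
    }
  }
  # every column except the one with the published duplicate (ds_2010 of
  # table3, printed with two 23s and no 24) is a permutation of 1..35
  for (nm in rank_fixtures) {
    fx <- load_fixture(nm)
    for (col in setdiff(names(fx)[-1], if (nm == "table3_norm_ranks") "ds_2010")) {
      expect_identical(sort(fx[[col]]), 1:35, info = paste(nm, col))
    }
  }
  t3 <- load_fixture("table3_norm_ranks")
  expect_identical(sum(t3$ds_2010 == 23), 2L)
  expect_false(24 %in% t3$ds_2010)

  # anti-drift: checksums of the packaged transcriptions
  files <- c("table1_scores.csv", "table2_groups.csv", "table3_norm_ranks.csv",
             "table4_weight_ranks.csv", "table5_agg_ranks.csv")
  sums <- unname(tools::md5sum(vapply(files, function(f) {
    system.file("extdata", f, package = "graphMCDM", mustWork = TRUE)
  }, character(1))))
  expect_identical(sums, c("28d2416045080bf3086e4bea30f44899",
                           "23d020a0bbbfe93995ee40792eab24cc",
                           "08987aef76483c40b2ecdd1352cbceb8",
                           "1be49880d5d9208ab9305a757c0cbff8",
                           "6d3f0fdc388bfa2cd4b971128ede97af"))
})

test_that("score tables and comparison reports round-trip through CSV", {
  dir <- withr::local_tempdir()
  set.seed(7)
  N <- rand_norm_matrix(3, 2, seed = 7)
  st <- waspas_score(N, new_test_weights(c(0.3, 0.7)), lambda = 0.4)
  p <- file.path(dir, "scores.csv")
  write_report(st, p)
  st2 <- read_score_table(p)
  expect_identical(st2$alternative, st$alternative)
  expect_identical(st2$rank, st$rank)
  expect_true(max(abs(st2$WQ - st$WQ)) <= 1e-12)
  expect_true(max(abs(st2$WS - st$WS)) <= 1e-12)
  expect_equal(attr(st2, "lambda"), 0.4, tolerance = 1e-15)

  # single-variant comparison report: 1x1 unit matrices
  g <- generate_decision_matrix(synthetic_spec(m = 10, n = 4, seed = 3))
  rep1 <- robustness_matrix(g$matrix, vary = "weighting",
                            config = pipeline_config(k = 3),
                            variants = "dcritic")
  expect_identical(dim(rep1$spearman), c(1L, 1L))
  expect_equal(rep1$spearman[1, 1], 1)
  expect_equal(rep1$vmeasure[1, 1], 1)
  write_report(rep1, file.path(dir, "cmp.csv"))
  expect_true(file.exists(file.path(dir, "cmp_spearman.csv")))
})
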