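test_that("attribute difference is the range-scaled absolute difference", {
  expect_equal(attribute_diff(5, 5, c(0, 10)), 0)
  expect_equal(attribute_diff(0, 10, c(0, 10)), 1)
  # hand arithmetic on the example rows: glucose 89 vs 197 in [0, 199]
  expect_equal(round(attribute_diff(89, 197, c(0, 199)), 5), 0.54271)
  expect_error(attribute_diff(1, 2, c(3, 3)), "zero span")
})

test_that("weights at k = 1 match the brute-force nearest-hit/miss oracle", {
  for (seed in 1:8) {
    n <- sample(8:30, 1)
    p <- sample(2:5, 1)
    x <- withr::with_seed(seed, matrix(runif(n * p), n, p))
    labels <- withr::with_seed(seed + 100, {
      l <- sample(c(0L, 1L), n, replace = TRUE)
      l[1:2] <- c(0L, 1L); l[3:4] <- c(0L, 1L)  # both classes with >= 2 members
      l
    })
    w <- relieff_weights(x, labels, k = 1)
    expect_equal(unname(w$weights), relief_oracle_k1(x, labels),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("a constant feature gets weight exactly zero", {
  x <- cbind(const = rep(3, 12), sig = c(rep(0, 6), rep(1, 6)))
  labels <- c(rep(0L, 6), rep(1L, 6))
  w <- relieff_weights(x, labels, k = 2)
  expect_identical(unname(w$weights[1]), 0)
  expect_gt(w$weights[2], 0)
})

test_that("a separating feature outweighs label-independent noise", {
  # 6 samples, feature 1 separates the classes, feature 2 is noise
  x <- cbind(f1 = c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0),
             f2 = c(0.3, 0.9, 0.1, 0.8, 0.2, 0.5))
  labels <- c(0L, 0L, 0L, 1L, 1L, 1L)
  w <- relieff_weights(x, labels, k = 1)
  expect_gt(w$weights[1], w$weights[2])
  expect_equal(unname(w$weights), relief_oracle_k1(x, labels), tolerance = 1e-12)
})

test_that("weights are bounded and equivariant under column permutation", {
  ft <- simulate_table(sim_spec(n_per_class = c(25, 20), informative = c(2, 5),
                                effect_size = 1.5, seed = 9))
  x <- feature_matrix(ft); labels <- table_labels(ft)
  w <- relieff_weights(x, labels, k = 4)
  expect_true(all(w$weights >= -1 & w$weights <= 1))

  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  wp <- relieff_weights(x[, perm], labels, k = 4)
  expect_equal(unname(wp$weights), unname(w$weights[perm]), tolerance = 1e-12)
})

test_that("class sizes below k + 1 are rejected with advice", {
  x <- matrix(runif(10), 5, 2)
  expect_error(relieff_weights(x, c(0, 0, 0, 1, 1), k = 2), "smaller k")
})

test_that("ranking sorts by descending weight with index tie-break", {
  expect_equal(rank_features(c(0.1, 0.3, 0.2)), c(2, 3, 1))
  expect_equal(rank_features(rep(0.5, 6)), 1:6)
  expect_equal(rank_features(c(b = 0.2, a = 0.2, c = 0.7)), c(3, 1, 2))
})

test_that("top-n selection returns the leading ranked indices", {
  w <- c(0.05, 0.4, -0.1, 0.4, 0.2)
  expect_equal(select_top(w, 1), 2)           # argmax, tie to lower index
  expect_equal(select_top(w, 5), c(2, 4, 5, 1, 3))
  expect_error(select_top(w, 6), "5")
})

test_that("tidy and CSV export carry feature, weight and rank", {
  ft <- example_clinical_rows()
  w <- relieff_weights(ft, k = 3)
  td <- tidy(w)
  expect_named(td, c("feature", "weight", "rank"))
  expect_equal(td$rank, 1:8)
  expect_equal(td$feature, feature_names(ft)[rank_features(w)])
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, path)
  back <- read.csv(path)
  expect_equal(back$feature_name, td$feature)
  expect_equal(back$weight, td$weight, tolerance = 1e-12)
})

test_that("deterministic subsampling: same seed, same weights", {
  ft <- simulate_table(sim_spec(n_per_class = c(40, 30), seed = 4))
  w1 <- relieff_weights(ft, k = 3, m = 20, seed = 7)
  w2 <- relieff_weights(ft, k = 3, m = 20, seed = 7)
  w3 <- relieff_weights(ft, k = 3, m = 20, seed = 8)
  expect_identical(w1$weights, w2$weights)
  expect_false(identical(w1$weights, w3$weights))
})
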