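# exhaustive partition check: every canvas pixel covered exactly once
layout_partition_ok <- function(lay) {
  w <- attr(lay, "width"); h <- attr(lay, "height")
  cover <- matrix(0L, h, w)
  for (i in seq_len(nrow(lay))) {
    cover[(lay$y0[i] + 1):lay$y1[i], (lay$x0[i] + 1):lay$x1[i]] <-
      cover[(lay$y0[i] + 1):lay$y1[i], (lay$x0[i] + 1):lay$x1[i]] + 1L
  }
  all(cover == 1L)
}

mirrored_cells <- function(lay, axis = c("h", "v")) {
  axis <- match.arg(axis)
  w <- attr(lay, "width"); h <- attr(lay, "height")
  if (axis == "h") {
    data.frame(x0 = w - lay$x1, y0 = lay$y0, x1 = w - lay$x0, y1 = lay$y1)
  } else {
    data.frame(x0 = lay$x0, y0 = h - lay$y1, x1 = lay$x1, y1 = h - lay$y0)
  }
}

cells_setequal <- function(a, b) {
  key <- function(d) sort(paste(d$x0, d$y0, d$x1, d$y1))
  identical(key(a), key(b))
}

test_that("single feature occupies the whole canvas", {
  lay <- build_layout(1, width = 50, height = 30)
  expect_equal(nrow(lay), 1)
  expect_equal(unname(c(lay$x0, lay$y0, lay$x1, lay$y1)), c(0, 0, 50, 30))
})

test_that("two equal masses split the default canvas into 60x120 halves", {
  lay <- build_layout(1:2, masses = c(1, 1))
  expect_equal(lay$area, c(7200, 7200))
  expect_equal(lay$x1[1], 60)
  expect_true(layout_partition_ok(lay))
})

test_that("eight rank-based cells tile the canvas with strictly ordered areas", {
  lay <- build_layout(c(2, 8, 6, 1, 7, 3, 5, 4))
  expect_equal(sum(lay$area), 120 * 120)
  expect_true(layout_partition_ok(lay))
  expect_true(all(diff(lay$area) < 0))     # rank-1 strictly largest
  expect_equal(lay$feature[1], 2)
})

test_that("partition, area monotonicity, asymmetry and determinism hold for p = 1..16", {
  for (p in 1:16) {
    lay <- build_layout(seq_len(p))
    expect_true(layout_partition_ok(lay), info = paste("p =", p))
    expect_equal(sum(lay$area), 14400, info = paste("p =", p))
    slack <- max(attr(lay, "width"), attr(lay, "height"))
    expect_true(all(diff(lay$area) <= slack), info = paste("p =", p))
    # proportionality up to the documented rounding slack
    exact <- 14400 * lay$mass / sum(lay$mass)
    expect_true(all(abs(lay$area - exact) <= slack), info = paste("p =", p))
    cells <- as.data.frame(lay[, c("x0", "y0", "x1", "y1")])
    if (p >= 2) {
      expect_false(cells_setequal(cells, mirrored_cells(lay, "h")),
                   info = paste("p =", p))
    }
    if (p >= 3) {  # a two-cell split is symmetric along its cut axis
      expect_false(cells_setequal(cells, mirrored_cells(lay, "v")),
                   info = paste("p =", p))
    }
    expect_identical(lay, build_layout(seq_len(p)))  # pure function
  }
})

test_that("random masses keep the partition and near-proportional areas", {
  for (seed in 1:5) {
    p <- 5 + seed
    masses <- withr::with_seed(seed, runif(p, 0.5, 3))
    ranking <- withr::with_seed(seed, sample(p))
    lay <- build_layout(ranking, masses = masses, width = 90, height = 70)
    expect_true(layout_partition_ok(lay))
    exact <- 90 * 70 * lay$mass / sum(lay$mass)
    expect_true(all(abs(lay$area - exact) <= max(90, 70)))
  }
})

test_that("degenerate layout inputs are rejected", {
  expect_error(build_layout(1:3, masses = c(1, 0, 1)), "positive")
  expect_error(build_layout(1:20, width = 10, height = 10), "too small")
  expect_error(build_layout(c(1, 3)))  # not a permutation
})

test_that("rasterization fills each cell with round-half-up intensities", {
  lay <- build_layout(c(2, 1, 3), width = 15, height = 15)
  img <- rasterize(c(1, 1, 1), lay)
  expect_true(all(unclass(img) == 255L))
  expect_true(all(unclass(rasterize(c(0, 0, 0), lay)) == 0L))

  img5 <- rasterize(c(0.5, 0.2, 0.9), lay)
  cell1 <- unclass(img5)[(lay$y0[lay$feature == 1] + 1):lay$y1[lay$feature == 1],
                         (lay$x0[lay$feature == 1] + 1):lay$x1[lay$feature == 1]]
  expect_true(all(cell1 == 128L))  # round_half_up(127.5)
  expect_error(rasterize(c(0.5, 0.2), lay), "3 cells")
  expect_error(rasterize(c(0.5, 0.2, 1.4), lay), "\\[0, 1\\]")
})

test_that("images are injective at the 1/255 resolution", {
  lay <- build_layout(1:4, width = 20, height = 20)
  base <- c(0.2, 0.4, 0.6, 0.8)
  img0 <- rasterize(base, lay)
  for (j in 1:4) {
    bumped <- base; bumped[j] <- bumped[j] + 1 / 255
    expect_false(identical(unclass(rasterize(bumped, lay)), unclass(img0)),
                 info = paste("feature", j))
  }
})

test_that("dataset conversion preserves counts, labels and bytes", {
  ft <- simulate_table(sim_spec(n_per_class = c(6, 4), seed = 3))
  nt <- minmax_normalize(ft)
  lay <- build_layout(rank_features(relieff_weights(ft, k = 2)),
                      width = 30, height = 30)
  dir <- withr::local_tempdir()
  man <- convert_dataset(nt, lay, out_dir = dir)
  expect_equal(nrow(man), 10)
  expect_equal(man$label, table_labels(ft))
  expect_true(all(file.exists(man$file)))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  # PNG round-trip and byte-identical re-runs
  back <- read_gray_png(man$file[1])
  expect_identical(px(back), px(man$image[[1]]))
  dir2 <- withr::local_tempdir()
  man2 <- convert_dataset(nt, lay, out_dir = dir2)
  expect_identical(unname(tools::md5sum(man$file)),
                   unname(tools::md5sum(man2$file)))

  one <- convert_dataset(nt[1:2, ], lay)  # subsetted tibble stays convertible
  expect_equal(nrow(one), 2)
})

test_that("layout JSON export round-trips the rectangles", {
  lay <- build_layout(c(3, 1, 2), width = 40, height = 20)
  js <- jsonlite::fromJSON(layout_to_json(lay))
  expect_equal(js$canvas$width, 40)
  expect_equal(js$cells$x1, lay$x1)
})
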