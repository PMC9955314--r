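test_that("fusion concatenates columns in order with matched rows", {
  a <- matrix(1:6, 2, 3); b <- matrix(7:10, 2, 2)
  f <- fuse_features(a, b)
  expect_equal(dim(f), c(2, 5))
  expect_equal(f[, 1:3], a)          # a's columns first, unchanged
  expect_equal(f[, 4:5], b)
  expect_equal(fuse_features(a, matrix(numeric(0), 2, 0)), a)
  expect_error(fuse_features(a, matrix(0, 3, 2)), "Row mismatch")
})

test_that("kernel SVMs behave classically on separable and XOR toys", {
  # linearly separable 4 points
  x <- rbind(c(0, 0), c(0, 1), c(3, 3), c(3, 4)); y <- c(0, 0, 1, 1)
  lin <- train_svm(x, y, "linear")
  expect_equal(predict(lin, x), y)

  # XOR: linear fails (<= 75%), quadratic succeeds
  xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)); yy <- c(0, 0, 1, 1)
  expect_lte(mean(predict(train_svm(xx, yy, "linear"), xx) == yy), 0.75)
  expect_equal(mean(predict(train_svm(xx, yy, "quadratic"), xx) == yy), 1)
  expect_equal(mean(predict(train_svm(xx, yy, "cubic"), xx) == yy), 1)

  # determinism
  set.seed(1); xg <- matrix(rnorm(60), 20, 3); yg <- rep(c(0, 1), 10)
  p1 <- predict(train_svm(xg, yg, "gaussian"), xg)
  p2 <- predict(train_svm(xg, yg, "gaussian"), xg)
  expect_identical(p1, p2)

  expect_error(train_svm(x, c(1, 1, 1, 1), "linear"), "single class")
  expect_error(train_svm(rbind(c(NA, 1), c(0, 1)), c(0, 1), "linear"),
               "non-finite")
})

test_that("confusion metrics match hand arithmetic and flag undefined ratios", {
  # perfect predictions
  r <- metrics_from_counts(tp = 30, tn = 50, fp = 0, fn = 0)
  expect_equal(r$accuracy, 100)
  expect_equal(c(r$specificity, r$precision, r$sensitivity, r$f1_score, r$mcc),
               rep(1, 5))
  expect_length(r$undefined, 0)

  # all-positive predictor on a balanced set
  r2 <- metrics_from_counts(tp = 50, tn = 0, fp = 50, fn = 0)
  expect_equal(r2$accuracy, 50)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$f1_score, 2 / 3)
  expect_true(is.na(r2$mcc))
  expect_equal(r2$undefined, "mcc")

  # constructed matrix, hand evaluation
  r3 <- metrics_from_counts(tp = 255, fn = 13, tn = 433, fp = 67)
  expect_equal(round(r3$accuracy, 2), 89.58)
  expect_equal(round(r3$sensitivity, 4), 0.9515)
  expect_equal(round(r3$specificity, 4), 0.8660)
  expect_equal(round(r3$f1_score, 4), round(2 * 255 / (2 * 255 + 67 + 13), 4))

  expect_error(evaluate_predictions(c(0, 1), c(0, 1, 1)), "same length")
  expect_error(evaluate_predictions(c(0, 2), c(0, 1)), "binary")
})

test_that("closed forms agree with independent counting on random trials", {
  for (trial in 1:200) {
    n <- 3 + (trial %% 40)
    pred <- withr::with_seed(trial, sample(c(0L, 1L), n, replace = TRUE))
    truth <- withr::with_seed(trial + 5000, sample(c(0L, 1L), n, replace = TRUE))
    got <- evaluate_predictions(pred, truth)
    want <- count_metrics_oracle(pred, truth)
    expect_equal(unname(got$confusion),
                 c(want$tp, want$tn, want$fp, want$fn))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$precision, want$precision)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$f1_score, want$f1)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
  }
})

test_that("MCC magnitude is invariant to swapping the positive class", {
  for (seed in 1:20) {
    n <- 30
    pred <- withr::with_seed(seed, sample(c(0L, 1L), n, replace = TRUE))
    truth <- withr::with_seed(seed + 99, sample(c(0L, 1L), n, replace = TRUE))
    m1 <- evaluate_predictions(pred, truth)$mcc
    m2 <- evaluate_predictions(1L - pred, 1L - truth)$mcc
    if (is.na(m1)) expect_true(is.na(m2)) else expect_equal(abs(m1), abs(m2))
    # swapping convention in both leaves MCC itself unchanged
    if (!is.na(m1)) expect_equal(m1, m2)
  }
})

test_that("toy confusion generators hit their closed-form metrics", {
  p <- toy_confusion("perfect", 10)
  expect_equal(evaluate_predictions(p$predicted, p$truth)$mcc, 1)
  i <- toy_confusion("inverted", 10)
  expect_equal(evaluate_predictions(i$predicted, i$truth)$mcc, -1)
  r <- toy_confusion("random", 10000, seed = 42)
  expect_lt(abs(evaluate_predictions(r$predicted, r$truth)$mcc), 0.05)
})

test_that("selected fusion keeps exactly n columns and is leakage-safe by default", {
  # 60 samples, 40 columns; 5 columns carry all the signal
  n <- 60; p <- 40
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- withr::with_seed(31, matrix(rnorm(n * p), n, p))
  x[labels == 1, 1:5] <- x[labels == 1, 1:5] + 2.5
  res <- selected_fusion_classify(x, labels, n_select = 5, kernel = "linear",
                                  k = 3, seed = 2)
  expect_length(res$selected, 5)
  expect_setequal(res$selected, 1:5)   # the informative columns are found
  expect_s3_class(res$report, "metrics_report")
  # weights were fitted on training rows only
  expect_equal(res$weights$n, length(res$train))

  # selecting the full dimension is the identity and skips no rows
  full <- selected_fusion_classify(x, labels, n_select = p, kernel = "linear",
                                   k = 3, seed = 2)
  direct <- train_svm(x[full$train, ], labels[full$train], "linear")
  expect_identical(full$predictions, predict(direct, x[full$test, ]))

  expect_error(selected_fusion_classify(x, labels, n_select = 99), "99")
})

test_that("informative selection beats random columns on held-out data", {
  # paired comparison over seeds: top-5 selected vs 5 random columns
  wins <- 0; trials <- 10
  for (seed in seq_len(trials)) {
    n <- 50; p <- 30
    labels <- rep(c(0L, 1L), each = n / 2)
    x <- withr::with_seed(400 + seed, matrix(rnorm(n * p), n, p))
    x[labels == 1, 1:5] <- x[labels == 1, 1:5] + 2
    sel <- selected_fusion_classify(x, labels, n_select = 5, kernel = "linear",
                                    k = 3, seed = seed)
    rand_cols <- withr::with_seed(900 + seed, sample(p, 5))
    sp <- list(train = sel$train, test = sel$test)
    clf <- train_svm(x[sp$train, rand_cols], labels[sp$train], "linear")
    acc_rand <- mean(predict(clf, x[sp$test, rand_cols]) == labels[sp$test])
    acc_sel <- sel$report$accuracy / 100
    if (acc_sel >= acc_rand) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.7 * trials))
})

test_that("stratified split respects class proportions and the seed", {
  labels <- c(rep(0L, 50), rep(1L, 30))
  sp <- stratified_split(labels, split = 0.8, seed = 3)
  expect_equal(length(sp$train), 64)
  expect_equal(sum(labels[sp$train] == 0), 40)
  expect_equal(sum(labels[sp$train] == 1), 24)
  expect_identical(sp, stratified_split(labels, split = 0.8, seed = 3))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
})
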