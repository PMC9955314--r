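# Backbone tests run at reduced input resolution: the penultimate feature
# dimension comes from global average pooling and is independent of input
# size, so the 512/2048 contracts hold at any admissible resolution.

test_that("adapted backbones expose the contracted feature dimensions", {
  m18 <- adapt_backbone(18, input_size = 32, seed = 1)
  m50 <- adapt_backbone(50, input_size = 32, seed = 1)
  expect_equal(m18$feature_dim, 512)
  expect_equal(m50$feature_dim, 2048)
  expect_false(m18$trained)
  expect_error(adapt_backbone(34), "depths are 18 and 50")
  expect_error(adapt_backbone(18, pretrained = TRUE), "weights_file")
})

test_that("preprocessing resizes, replicates channels and fixes intensity scale", {
  lay <- build_layout(1:4)
  img <- rasterize(c(0.2, 0.5, 0.8, 0.1), lay)     # 120 x 120
  x <- preprocess_images(list(img), size = 224)
  expect_equal(dim(x), c(224, 224, 3, 1))

  # constant image of value v stays v in every channel after bilinear resize
  flat <- tab2img:::gray_image(matrix(102L, 40, 40))
  xf <- preprocess_images(list(flat), size = 64)
  expect_equal(range(xf), rep(102 / 255, 2), tolerance = 1e-12)
  zero <- tab2img:::gray_image(matrix(0L, 40, 40))
  expect_true(all(preprocess_images(list(zero), size = 64) == 0))

  # channel replication: all three channels identical
  expect_equal(x[, , 1, 1], x[, , 2, 1])
  expect_equal(x[, , 1, 1], x[, , 3, 1])

  # standardized variant shifts each channel by its own statistics
  xs <- preprocess_images(list(flat), size = 32, normalize = "imagenet")
  expect_equal(mean(xs[, , 1, 1]), (102 / 255 - 0.485) / 0.229, tolerance = 1e-12)
})

test_that("the learning-rate schedule drops by the factor every period", {
  cfg <- train_config()
  expect_equal(schedule_lr(cfg, 1), 0.001)
  expect_equal(schedule_lr(cfg, 5), 0.001)   # never drops within 5 epochs
  expect_equal(schedule_lr(cfg, 20), 0.001)
  expect_equal(schedule_lr(cfg, 21), 0.0001)
  expect_equal(schedule_lr(cfg, 41), 0.00001)
})

test_that("training records one curve row per epoch and learns on a fixture", {
  fix <- separable_images(n_per_class = 10, side = 24, seed = 3)  # 20 images
  m <- adapt_backbone(18, input_size = 24, seed = 2)
  cfg <- train_config(max_epochs = 5, batch_size = 8, initial_lr = 0.01, seed = 5)
  tr <- train_backbone(m, fix$images, fix$labels, cfg)
  h <- tidy(tr)
  expect_equal(nrow(h), 5)
  expect_equal(h$lr, rep(0.01, 5))
  expect_gte(h$train_accuracy[5], h$train_accuracy[1])
  expect_true(tr$trained)
  expect_equal(glance(tr)$epochs, 5)
  expect_error(train_backbone(m, fix$images, rep(1, 20), cfg), "single class")
})

test_that("a depth-18 network can memorize a 16-image fixture", {
  fix <- separable_images(n_per_class = 8, side = 24, seed = 7)
  m <- adapt_backbone(18, input_size = 24, seed = 4)
  cfg <- train_config(max_epochs = 10, batch_size = 4, initial_lr = 0.01, seed = 6)
  tr <- train_backbone(m, fix$images, fix$labels, cfg)
  expect_equal(max(tidy(tr)$train_accuracy), 1)
  # and the trained model separates the training set at prediction time
  expect_gte(mean(predict(tr, fix$images) == fix$labels), 0.9)
})

test_that("feature extraction is shaped by the manifest and is deterministic", {
  fix <- separable_images(n_per_class = 5, side = 24, seed = 9)
  m18 <- adapt_backbone(18, input_size = 24, seed = 3)
  f <- extract_features(m18, fix$images)
  expect_equal(dim(f), c(10, 512))
  expect_identical(f, extract_features(m18, fix$images))  # pure function
  # duplicate image -> identical feature rows
  dup <- extract_features(m18, fix$images[c(1, 1)])
  expect_identical(dup[1, ], dup[2, ])
  # empty input -> 0 x d matrix
  expect_equal(dim(extract_features(m18, list())), c(0, 512))

  m50 <- adapt_backbone(50, input_size = 24, seed = 3)
  expect_equal(dim(extract_features(m50, fix$images[1:3])), c(3, 2048))
})

test_that("training is reproducible for a fixed seed", {
  fix <- separable_images(n_per_class = 4, side = 24, seed = 10)
  cfg <- train_config(max_epochs = 2, batch_size = 4, initial_lr = 0.01, seed = 8)
  tr1 <- train_backbone(adapt_backbone(18, input_size = 24, seed = 5),
                        fix$images, fix$labels, cfg)
  tr2 <- train_backbone(adapt_backbone(18, input_size = 24, seed = 5),
                        fix$images, fix$labels, cfg)
  expect_identical(rlang::hash(tr1$net), rlang::hash(tr2$net))
  expect_equal(tidy(tr1), tidy(tr2))
})

test_that("checkpoints round-trip through disk", {
  m <- adapt_backbone(18, input_size = 24, seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_backbone(m, path)
  m2 <- adapt_backbone(18, pretrained = TRUE, weights_file = path)
  fix <- separable_images(n_per_class = 3, side = 24, seed = 12)
  expect_identical(extract_features(m, fix$images[1:2]),
                   extract_features(m2, fix$images[1:2]))
})
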