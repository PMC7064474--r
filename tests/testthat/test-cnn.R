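# tiny architecture used throughout: patch 23 keeps the conv/pool stack
# valid while making desk-scale training fast
tiny_cfg <- function(...) {
  args <- list(patch_size = 23, filters = c(4L, 4L, 8L, 8L),
               dense = 32, dropout = 0.2, learning_rate = 0.05,
               lr_decay = 0.7, batch_size = 64, epochs = 5, seed = 9)
  over <- list(...)
  args[names(over)] <- over
  do.call(classifier_config, args)
}

# four classes with disjoint mean intensities plus noise
separable_patches <- function(n, size = 23, seed = 1) {
  set.seed(seed)
  y <- rep(1:4, length.out = n)
  mu <- c(-1.5, -0.5, 0.5, 1.5)
  x <- matrix(rnorm(n * size^2, mean = mu[y], sd = 0.3), n, size^2)
  list(x = x, y = y)
}

test_that("the classifier separates classes with disjoint intensities", {
  tr <- separable_patches(1600, seed = 1)
  va <- separable_patches(400, seed = 2)
  m <- train_classifier(tr, va, tiny_cfg())
  expect_gte(max(m$history$val_accuracy), 0.95)
  p <- predict_patches(m, va$x)
  expect_equal(rowSums(p), rep(1, 400), tolerance = 1e-5)
})

test_that("training is deterministic for a fixed seed", {
  tr <- separable_patches(400, seed = 3)
  va <- separable_patches(100, seed = 4)
  cfg <- tiny_cfg(epochs = 1)
  m1 <- train_classifier(tr, va, cfg)
  m2 <- train_classifier(tr, va, cfg)
  expect_identical(m1$history$initial_loss, m2$history$initial_loss)
  expect_identical(m1$weights$W1, m2$weights$W1)
  expect_identical(m1$history$val_accuracy, m2$history$val_accuracy)
})

test_that("an untrained model sits at chance on a balanced set", {
  tr <- separable_patches(400, seed = 5)
  va <- separable_patches(400, seed = 6)
  m <- train_classifier(tr, va, tiny_cfg(epochs = 0))
  p <- predict_patches(m, va$x)
  acc <- mean(max.col(p, ties.method = "first") == va$y)
  expect_lt(abs(acc - 0.25), 0.15)
})

test_that("missing classes and shape mismatches are rejected", {
  tr <- separable_patches(400, seed = 7)
  tr$y[tr$y == 2] <- 1   # drop nucleus_border
  va <- separable_patches(100, seed = 8)
  expect_error(train_classifier(tr, va, tiny_cfg()), "nucleus_border")
  tr2 <- separable_patches(100, seed = 7)
  expect_error(train_classifier(tr2, va,
                                tiny_cfg(patch_size = 27)), "patch size")
})

test_that("semantic prediction labels every pixel with tie-broken argmax", {
  tr <- separable_patches(1200, seed = 9)
  va <- separable_patches(300, seed = 10)
  m <- train_classifier(tr, va, tiny_cfg(epochs = 3))
  img <- matrix(rnorm(30 * 24, mean = 1.5, sd = 0.3), 30, 24)  # class 4 field
  out <- predict_semantic_map(m, img)
  expect_equal(dim(out$map), c(30, 24))
  expect_true(all(out$map %in% semantic_classes()))
  expect_equal(apply(out$prob, c(1, 2), sum),
               matrix(1, 30, 24), tolerance = 1e-5)
  # majority of this uniform background field should be background
  expect_gt(mean(out$map == semantic_classes()[["background"]]), 0.9)
  # tie-break: equal probabilities pick the first class (nucleus)
  probs <- matrix(0.25, 2, 4)
  expect_equal(max.col(probs, ties.method = "first"), c(1, 1))
})

test_that("models serialize and restore exactly", {
  tr <- separable_patches(300, seed = 11)
  va <- separable_patches(100, seed = 12)
  stats <- fit_position_stats(matrix(rnorm(50 * 23^2), 50, 23^2))
  m <- train_classifier(tr, va, tiny_cfg(epochs = 1), stats = stats)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$stats$mean, m$stats$mean, tolerance = 1e-12)
  expect_equal(predict_patches(m2, va$x), predict_patches(m, va$x),
               tolerance = 1e-12)
  unlink(f)
})
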