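test_that("optical density follows the base-10 Beer-Lambert law", {
  px <- array(c(255, 25.5, 0), c(1, 1, 3))
  od <- rgb_to_optical_density(px)
  expect_equal(od[1, 1, 1], 0)
  expect_equal(od[1, 1, 2], 1)                  # -log10(0.1)
  expect_equal(od[1, 1, 3], log10(255))         # clamped to 1, finite
  expect_true(all(is.finite(od)))
  expect_error(rgb_to_optical_density(px, i0 = 0), "positive")
  expect_error(rgb_to_optical_density(px, i0 = -3), "positive")
})

test_that("optical density is monotone decreasing in intensity", {
  i <- seq(1, 255, by = 2)
  img <- array(rep(i, 3), c(length(i), 1, 3))
  od <- rgb_to_optical_density(img)
  expect_true(all(diff(od[, 1, 1]) < 0))
})

test_that("stain matrix is unit-norm with a positive residual column", {
  W <- stain_matrix_he()
  expect_equal(unname(colSums(W^2)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(W >= 0))
  expect_equal(colnames(W), c("hematoxylin", "eosin", "residual"))
  expect_gt(abs(det(W)), 1e-3)
})

test_that("deconvolution inverts the forward model exactly", {
  W <- stain_matrix_he()
  # zero OD -> zero concentrations
  z <- deconvolve(array(0, c(4, 5, 3)))
  expect_true(all(vapply(z, function(m) all(m == 0), TRUE)))
  # pure hematoxylin pixel
  od1 <- array(rep(0.7 * W[, 1], each = 1), c(1, 1, 3))
  r1 <- deconvolve(od1)
  expect_equal(r1$hematoxylin[1, 1], 0.7, tolerance = 1e-6)
  expect_equal(r1$eosin[1, 1], 0, tolerance = 1e-6)
  # round trip on 1000 random pixels with concentrations in [0, 2]
  set.seed(41)
  Hc <- matrix(runif(3000, 0, 2), nrow = 3)
  m <- W %*% Hc
  od <- array(0, c(10, 100, 3))
  for (ch in 1:3) od[, , ch] <- matrix(m[ch, ], 10, 100)
  rec <- deconvolve(od)
  for (k in 1:3)
    expect_lt(max(abs(rec[[k]] - matrix(Hc[k, ], 10, 100))), 1e-6)
})

test_that("deconvolution is linear and rejects rank-deficient matrices", {
  set.seed(5)
  od1 <- array(runif(60), c(4, 5, 3))
  od2 <- array(runif(60), c(4, 5, 3))
  a <- 0.3; b <- 1.7
  lhs <- deconvolve(a * od1 + b * od2)
  r1 <- deconvolve(od1); r2 <- deconvolve(od2)
  for (k in 1:3)
    expect_equal(lhs[[k]], a * r1[[k]] + b * r2[[k]], tolerance = 1e-9)
  Wbad <- stain_matrix_he()
  Wbad[, 2] <- Wbad[, 1]
  expect_error(deconvolve(od1, Wbad), "collinear")
})

test_that("position statistics use the population convention with a floor", {
  p <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3, byrow = FALSE)
  # identical patches -> sd at floor
  s <- fit_position_stats(p)
  expect_equal(unname(s$mean[1, 1]), 1)
  expect_true(all(s$sd == 1e-6))
  # two patches with values 0 and 2 -> mean 1, sd 1 (divide by N)
  s2 <- fit_position_stats(rbind(rep(0, 4), rep(2, 4)))
  expect_true(all(s2$mean == 1))
  expect_true(all(s2$sd == 1))
  expect_error(fit_position_stats(p[1, , drop = FALSE]), "at least 2")
})

test_that("position statistics recover simulated moments", {
  set.seed(7)
  n <- 10000; size <- 5
  mu <- matrix(runif(size^2, -1, 1), size, size)
  sigma <- matrix(runif(size^2, 0.5, 2), size, size)
  x <- matrix(rnorm(n * size^2), n, size^2)
  x <- sweep(sweep(x, 2, as.vector(sigma), "*"), 2, as.vector(mu), "+")
  s <- fit_position_stats(x)
  se_mean <- sigma / sqrt(n)
  se_sd <- sigma / sqrt(2 * n)
  expect_true(all(abs(s$mean - mu) < 3 * se_mean + 1e-12))
  expect_true(all(abs(s$sd - sigma) < 3 * se_sd + 1e-2))
})

test_that("standardization centers and scales per position", {
  set.seed(8)
  x <- matrix(rnorm(200 * 9, 5, 2), 200, 9)
  s <- fit_position_stats(x)
  expect_equal(standardize(s$mean, s), matrix(0, 3, 3))
  expect_equal(standardize(s$mean + s$sd, s), matrix(1, 3, 3))
  z <- standardize(x, s)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(z^2)) - 1)), 1e-10)
  expect_error(standardize(matrix(0, 4, 4), s), "match")
})
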