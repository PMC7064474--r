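test_that("distance map is exact Euclidean distance to background", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_equal(distance_map(m)[5, 5], 1)
  d <- disc_mask(41, 41, 21, 21, 15)
  dm <- distance_map(d)
  expect_equal(which(dm == max(dm)), which(matrix(seq_len(41^2), 41) ==
                                             (21 - 1) * 41 + 21))
  expect_true(abs(max(dm) - 15) <= 1.5)
  expect_true(all(dm[d == 0] == 0))
  set.seed(31)
  for (i in 1:6) {
    m <- rand_mask(40, 40, runif(1, 0.3, 0.9))
    expect_equal(distance_map(m), oracle_edt(m))
  }
})

test_that("geodesic dilation is elementary dilation clipped by the mask", {
  mk <- matrix(c(0, 0, 2, 0, 0), 1, 5)
  ms <- matrix(c(1, 2, 2, 2, 1), 1, 5)
  expect_equal(geodesic_dilate(mk, ms), matrix(c(0, 2, 2, 2, 0), 1, 5))
  # fixed point and annihilator
  expect_equal(geodesic_dilate(ms, ms), ms)
  expect_equal(geodesic_dilate(0 * ms, ms), 0 * ms)
  expect_error(geodesic_dilate(ms + 1, ms), "<=")
})

test_that("iterated geodesic dilation reproduces the hand-iterated profile", {
  mask <- matrix(c(0, 1, 2, 3, 2, 1, 0, 2, 3, 2, 0), 1, 11)
  marker <- matrix(0, 1, 11); marker[1, 4] <- 3
  cur <- marker
  for (i in 1:20) cur <- geodesic_dilate(cur, mask)
  expect_equal(cur, matrix(c(0, 1, 2, 3, 2, 1, 0, 0, 0, 0, 0), 1, 11))
  expect_equal(reconstruct(marker, mask), cur)
})

test_that("reconstruction is an idempotent fixpoint between marker and mask", {
  set.seed(32)
  for (i in 1:20) {
    mask <- matrix(sample(0:8, 24 * 24, replace = TRUE), 24, 24)
    marker <- pmin(matrix(sample(0:8, 24 * 24, replace = TRUE), 24, 24),
                   mask)
    storage.mode(mask) <- "double"; storage.mode(marker) <- "double"
    r <- reconstruct(marker, mask)
    expect_equal(r, oracle_reconstruct(marker, mask))
    expect_true(all(r >= marker) && all(r <= mask))
    expect_equal(reconstruct(r, mask), r)  # idempotent
  }
  # increasing in both arguments
  mask <- matrix(runif(100, 0, 4), 10, 10)
  m1 <- pmin(matrix(runif(100, 0, 4), 10, 10), mask)
  m2 <- pmin(m1 + runif(100, 0, 0.5), mask)
  expect_true(all(reconstruct(m1, mask) <= reconstruct(m2, mask)))
  expect_true(all(reconstruct(m1, mask) <=
                    reconstruct(m1, mask + 0.3) + 1e-12))
})

test_that("seed imposition suppresses unseeded maxima only", {
  mask <- matrix(c(0, 1, 2, 3, 2, 1, 0, 2, 3, 2, 0), 1, 11)
  dummy <- matrix(0L, 1, 11)
  # seeds on every maximum: map unchanged
  s_all <- dummy; s_all[1, c(4, 9)] <- 1L
  expect_equal(impose_seeds(mask, s_all), mask)
  # seed on one peak only: the other is flattened to its saddle
  s1 <- dummy; s1[1, 4] <- 1L
  imp <- impose_seeds(mask, s1)
  expect_equal(imp, matrix(c(0, 1, 2, 3, 2, 1, 0, 0, 0, 0, 0), 1, 11))
  # on the full domain the only surviving regional maximum is the seeded
  # peak (the flattened lobe has merged with its saddle)
  mx <- regional_maxima(imp, matrix(1L, 1, 11))
  expect_equal(which(mx > 0), 4L)
  expect_error(impose_seeds(mask, dummy), "empty")
  bad <- dummy; bad[1, 1] <- 1L   # on background
  expect_error(impose_seeds(mask, bad), "outside")
})

test_that("flood partitions the mask into one basin per seed component", {
  blob <- pmax(disc_mask(60, 90, 30, 30, 16), disc_mask(60, 90, 30, 56, 16))
  storage.mode(blob) <- "integer"
  tm <- distance_map(blob)
  # one seed -> one region covering the mask
  s1 <- matrix(0L, 60, 90); s1[30, 30] <- 1L
  f1 <- flood(impose_seeds(tm, s1), s1, blob)
  expect_equal(sort(unique(as.vector(f1[blob == 1]))), 1L)
  # conditional-erosion seeds -> exactly two basins that partition
  seeds <- conditional_erode(blob)
  f2 <- flood(impose_seeds(tm, seeds), seeds, blob)
  expect_equal(max(f2), 2L)
  expect_equal(sum(f2 > 0), sum(blob))
  expect_true(all(tabulate(f2[f2 > 0], 2) > 0))
  expect_error(flood(tm, matrix(0L, 60, 90), blob), "empty")
})

test_that("flooding is deterministic", {
  set.seed(33)
  blob <- generate_clump(3, seed = 77)$mask
  seeds <- conditional_erode(blob)
  tm <- impose_seeds(distance_map(blob), seeds)
  expect_identical(flood(tm, seeds, blob), flood(tm, seeds, blob))
})
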