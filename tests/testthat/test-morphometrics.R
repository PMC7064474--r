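test_that("component labeling follows connectivity and raster order", {
  expect_equal(max(label_components(matrix(0L, 5, 5))), 0)
  m <- matrix(0L, 4, 4); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(attr(label_components(m, 8), "n"), 1L)
  expect_equal(attr(label_components(m, 4), "n"), 2L)
  # raster order of first pixels
  m2 <- matrix(0L, 5, 5); m2[1, 4] <- 1L; m2[3, 1] <- 1L
  lab <- label_components(m2)
  expect_equal(lab[1, 4], 1L)
  expect_equal(lab[3, 1], 2L)
})

test_that("component count matches the flood-fill oracle on random scenes", {
  set.seed(11)
  for (i in 1:12) {
    m <- matrix(0L, 40, 50)
    for (r in 1:8) {
      y <- sample(1:34, 1); x <- sample(1:42, 1)
      m[y:(y + sample(2:6, 1)), x:(x + sample(2:8, 1))] <- 1L
    }
    for (conn in c(4, 8))
      expect_equal(attr(label_components(m, conn), "n"),
                   oracle_component_count(m, conn))
  }
})

test_that("roundness uses 4*pi*A/P^2 and matches a contour-walk oracle", {
  # analytic circle: roundness exactly 1
  A <- pi * 10^2; P <- 2 * pi * 10
  expect_equal(4 * pi * A / P^2, 1)
  # digital disc r = 25 against the independent contour-walk estimate
  d <- ellipse_mask(61, 61, 31, 31, 25, 25)
  rec <- measure(label_components(d))
  expect_equal(rec$area, sum(d))
  p_walk <- oracle_contour_perimeter(d)
  expect_lt(abs(rec$perimeter - p_walk) / p_walk, 0.02)
  r_walk <- 4 * pi * rec$area / p_walk^2
  expect_lt(abs(rec$roundness - r_walk) / r_walk, 0.05)
  expect_lt(abs(rec$roundness - 1), 0.05)
})

test_that("elongated shapes fall below the roundness gate", {
  line <- matrix(0L, 10, 60); line[5, 6:55] <- 1L
  rec <- measure(label_components(line))
  expect_lt(rec$roundness, 0.31)
})

test_that("roundness stays below 1 + eps on random convex shapes", {
  set.seed(12)
  worst <- 0
  for (i in 1:200) {
    a <- runif(1, 6, 28); b <- a / runif(1, 1, 2.5)
    e <- ellipse_mask(70, 70, 35, 35, a, b, runif(1, 0, pi))
    r <- measure(label_components(e))$roundness
    worst <- max(worst, r)
  }
  expect_lt(worst, 1.05)
})

test_that("areas are conserved and labels partition the mask", {
  set.seed(13)
  m <- rand_mask(60, 60, 0.4)
  lab <- label_components(m)
  rec <- measure(lab)
  expect_equal(sum(rec$area), sum(m))
  expect_true(all(sort(unique(as.vector(lab[lab > 0]))) ==
                    seq_len(nrow(rec))))
})

test_that("gating separates single, clump and debris", {
  rule <- gating_rule()
  recs <- data.frame(area = c(5000, 12000, 100, 4000, 500),
                     roundness = c(0.8, 0.4, 0.9, 0.2, 0.995))
  got <- classify_objects(recs, rule)
  expect_equal(got, c("single", "clump", "debris", "clump", "clump"))
  # total and deterministic: exactly one outcome each
  expect_true(all(got %in% c("single", "clump", "debris")))
  expect_error(gating_rule(area_min = 10, area_max = 5), "area_min")
})
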