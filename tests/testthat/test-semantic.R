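make_ref_scene <- function() {
  # 30x30 toy stain + semantic map with all four classes
  sem <- matrix(1L, 30, 30)
  sem[5:25, 5:14] <- 2L
  nuc <- ellipse_mask(30, 30, 15, 22, 6, 5)
  ring <- nuc - erode(nuc, se_fine())
  sem[nuc == 1L] <- 3L
  sem[ring == 1L] <- 4L
  stain <- 0.05 + 0.1 * (sem == 2L) + 0.9 * (sem == 3L) + 0.5 * (sem == 4L)
  list(stain = stain, sem = sem)
}

test_that("patch extraction yields one labeled patch per annotated pixel", {
  sc <- make_ref_scene()
  ps <- extract_patches(sc$stain, sc$sem, size = 9)
  expect_equal(length(ps$y), 900)            # all pixels annotated
  expect_equal(ncol(ps$x), 81)
  # indeterminate pixels are excluded
  sem2 <- sc$sem; sem2[1:10, 1:10] <- 0L
  ps2 <- extract_patches(sc$stain, sem2, size = 9)
  expect_equal(length(ps2$y), 800)
  # corner patch has full shape through reflection
  corner <- extract_patches(sc$stain, sc$sem, size = 9,
                            positions = cbind(1L, 1L))
  expect_equal(ncol(corner$x), 81)
  expect_true(all(is.finite(corner$x)))
  expect_error(extract_patches(sc$stain, sc$sem, size = 8), "odd")
})

test_that("patch labels follow the central pixel", {
  sc <- make_ref_scene()
  pos <- rbind(c(15L, 22L), c(2L, 2L), c(15L, 8L))
  ps <- extract_patches(sc$stain, sc$sem, size = 9, positions = pos)
  expect_equal(names(semantic_classes())[ps$y],
               c("nucleus", "background", "cytoplasm"))
})

test_that("augmentation rebalances the border class deterministically", {
  sc <- make_ref_scene()
  ps <- extract_patches(sc$stain, sc$sem, size = 9)
  n_border <- sum(ps$y == 2)
  expect_gt(n_border, 0)
  a1 <- augment(ps, factor = 4, seed = 5)
  a2 <- augment(ps, factor = 4, seed = 5)
  expect_identical(a1$x, a2$x)                         # determinism
  expect_equal(sum(a1$y == 2), 4 * n_border)           # enlarged 4x
  for (k in c(1, 3, 4))
    expect_equal(sum(a1$y == k), sum(ps$y == k))       # counts preserved
  # identity contract
  expect_identical(augment(ps, factor = 1, transform_in_place = FALSE), ps)
  # labels never change
  expect_equal(a1$y[seq_along(ps$y)], ps$y)
})

test_that("augmentation warns when there is nothing to augment", {
  sc <- make_ref_scene()
  keep <- which(sc$sem != 4L)
  sem2 <- sc$sem; sem2[sc$sem == 4L] <- 0L
  ps <- extract_patches(sc$stain, sem2, size = 9)
  expect_warning(out <- augment(ps, factor = 4), "no nucleus_border")
  expect_identical(out, ps)
})

test_that("nuclei mask keeps interiors and drops border rings", {
  sem <- matrix(1L, 12, 12)
  expect_equal(sum(mask_from_semantic(sem)), 0)
  sc <- make_ref_scene()
  m <- mask_from_semantic(sc$sem)
  expect_setequal(unique(as.vector(m)), c(0L, 1L))
  expect_equal(sum(m), sum(sc$sem == 3L))
  # two nuclei separated by a 1 px border line -> 2 components
  sem2 <- matrix(1L, 20, 20)
  sem2[5:15, 4:9] <- 3L; sem2[5:15, 11:16] <- 3L; sem2[5:15, 10] <- 4L
  expect_equal(attr(label_components(mask_from_semantic(sem2)), "n"), 2L)
  expect_equal(attr(label_components(
    mask_from_semantic(sem2, include_border = TRUE)), "n"), 1L)
})

test_that("Otsu threshold lands between well-separated modes", {
  set.seed(44)
  img <- matrix(sample(c(0.1, 0.9), 400, replace = TRUE), 20, 20)
  m <- mask_otsu(img)
  thr <- attr(m, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  expect_equal(m, matrix(as.integer(img > 0.5), 20, 20),
               ignore_attr = TRUE)
  expect_warning(m0 <- mask_otsu(matrix(1, 5, 5)), "constant")
  expect_equal(sum(m0), 0)
})

test_that("adaptive threshold responds to local contrast", {
  img <- matrix(0.02, 40, 40)
  img[10:20, 10:20] <- 1
  m <- mask_adaptive(img, window = 21, offset = -0.05)
  expect_true(all(m[12:18, 12:18] == 1L))
  expect_true(all(m[30:40, 30:40] == 0L))
  expect_error(mask_adaptive(img, window = 20), "odd")
})
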