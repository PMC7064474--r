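small_spec <- function(...) {
  scene_spec(width = 420, height = 420, n_nuclei = 5,
             overlap_fraction = 0.2, seed = 61, ...)
}

test_that("an empty scene is blank", {
  sc <- generate_scene(scene_spec(n_nuclei = 0, width = 80, height = 80))
  expect_equal(sum(sc$mask), 0)
  expect_equal(max(sc$labels), 0)
  expect_true(all(sc$semantic == 1L))
  expect_equal(dim(sc$rgb), c(80, 80, 3))
})

test_that("non-overlapping scenes have one component per nucleus", {
  sc <- generate_scene(scene_spec(width = 800, height = 800, n_nuclei = 8,
                                  overlap_fraction = 0, seed = 62))
  expect_equal(attr(label_components(sc$mask), "n"), 8L)
  rec <- measure(sc$labels)
  expect_true(all(rec$area >= 309 & rec$area <= 7801))
  expect_true(all(classify_objects(rec) == "single"))
})

test_that("generation is deterministic given the seed", {
  s1 <- generate_scene(small_spec())
  s2 <- generate_scene(small_spec())
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$semantic, s2$semantic)
  c1 <- generate_clump(2, seed = 9); c2 <- generate_clump(2, seed = 9)
  expect_identical(c1$mask, c2$mask)
})

test_that("ground truth layers are mutually consistent", {
  sc <- generate_scene(small_spec())
  expect_equal(sc$mask, matrix(as.integer(sc$labels > 0), nrow(sc$labels),
                               ncol(sc$labels)))
  # label mask is the z-order resolution of the silhouette list: every
  # silhouette pixel is claimed by its own or a later (higher z) nucleus,
  # and label-i pixels always lie inside silhouette i
  for (i in seq_along(sc$silhouettes)) {
    px <- sc$silhouettes[[i]]
    expect_true(all(sc$labels[px] >= i))
    own <- which(sc$labels == i)
    expect_true(all(own %in% ((px[, 2] - 1L) * nrow(sc$labels) + px[, 1])))
  }
  # semantic nucleus+border pixels exactly cover the mask
  expect_equal(sort(unique(as.vector(sc$semantic))), 1:4)
  expect_equal(matrix(as.integer(sc$semantic %in% c(3L, 4L)),
                      nrow(sc$mask), ncol(sc$mask)), sc$mask)
})

test_that("clump fixtures are connected with the stated count", {
  for (k in 2:3) {
    cl <- generate_clump(k, seed = 63 + k)
    expect_equal(cl$k, k)
    expect_equal(attr(label_components(cl$mask), "n"), 1L)
    expect_equal(nrow(cl$centers), k)
  }
})

test_that("rendering round-trips through deconvolution within noise", {
  sc <- generate_scene(small_spec())
  hema <- hematoxylin_image(sc$rgb)
  interior <- erode(sc$mask, se_coarse()) == 1L  # away from blurred edges
  planted <- 1.0  # nucleus hematoxylin, +-10% per-nucleus jitter
  expect_lt(abs(mean(hema[interior]) - planted), 0.12)
  bg <- sc$semantic == 1L
  expect_lt(mean(hema[bg]), 0.1)
})

test_that("patch corpora are balanced and split by scene", {
  scenes <- lapply(1:4, function(s)
    generate_scene(scene_spec(width = 420, height = 420, n_nuclei = 4,
                              overlap_fraction = 0.25, seed = 70 + s)))
  corpus <- generate_patch_corpus(scenes, size = 23, n_per_class = 40,
                                  val_scenes = 3:4, seed = 64)
  expect_equal(dim(corpus$counts), c(2L, 4L))
  expect_true(all(corpus$counts > 0))
  expect_equal(sum(corpus$counts["train", ]), length(corpus$train$y))
  # standardized: overall means near 0
  expect_lt(max(abs(colMeans(corpus$train$x))), 0.5)
  expect_equal(corpus$stats$size, 23L)
})
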