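test_that("hausdorff matches closed forms and the brute-force oracle", {
  a <- disc_mask(20, 20, 10, 10, 5)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(rbind(c(1, 1)), rbind(c(4, 5))), 5)  # 3-4-5
  set.seed(51)
  for (i in 1:30) {
    ca <- cbind(sample(1:40, 12, TRUE), sample(1:40, 12, TRUE))
    cb <- cbind(sample(1:40, 9, TRUE), sample(1:40, 9, TRUE))
    expect_equal(hausdorff(ca, cb), oracle_hausdorff(ca, cb))
  }
  expect_error(hausdorff(matrix(0L, 3, 3), a), "empty")
})

test_that("hausdorff satisfies the metric axioms on random triples", {
  set.seed(52)
  for (i in 1:25) {
    s <- lapply(1:3, function(j)
      cbind(sample(1:30, 8, TRUE), sample(1:30, 8, TRUE)))
    dab <- hausdorff(s[[1]], s[[2]])
    dba <- hausdorff(s[[2]], s[[1]])
    dac <- hausdorff(s[[1]], s[[3]])
    dcb <- hausdorff(s[[3]], s[[2]])
    expect_equal(dab, dba)                       # symmetry
    expect_gte(dab, 0)
    expect_lte(dab, dac + dcb + 1e-9)            # triangle inequality
    expect_equal(hausdorff(s[[1]], s[[1]]), 0)   # identity
  }
})

test_that("jaccard distance follows the closed forms", {
  sq <- matrix(0L, 20, 30); sq[5:14, 5:14] <- 1L
  expect_equal(jaccard_distance(sq, sq), 0)
  off <- matrix(0L, 20, 30); off[5:14, 20:29] <- 1L
  expect_equal(jaccard_distance(sq, off), 1)    # disjoint
  sh <- matrix(0L, 20, 30); sh[5:14, 10:19] <- 1L
  expect_equal(jaccard_distance(sq, sh), 2 / 3) # 10x10 shifted 5 px
})

test_that("matching counts reconcile and respect the threshold", {
  labs <- matrix(0L, 40, 60)
  labs[5:14, 5:14] <- 1L; labs[20:29, 20:29] <- 2L; labs[5:14, 40:49] <- 3L
  ref <- object_set(labs)
  rep0 <- match_objects(ref, labs, metric = "jaccard")
  expect_equal(rep0$tp, 3); expect_equal(rep0$fp, 0); expect_equal(rep0$fn, 0)
  expect_equal(rep0$tp_rate, 1); expect_equal(rep0$fp_rate, 0)
  # a single pair at HD 35 under threshold 30 -> 1 FN and 1 FP
  a <- matrix(0L, 50, 90); a[20:24, 11:15] <- 1L
  b <- matrix(0L, 50, 90); b[20:24, 46:50] <- 1L
  expect_equal(hausdorff(a, b), 35)
  rep1 <- match_objects(object_set(list(a)), object_set(list(b)),
                        metric = "hausdorff", threshold = 30)
  expect_equal(c(rep1$tp, rep1$fp, rep1$fn), c(0, 1, 1))
  rep2 <- match_objects(object_set(list(a)), object_set(list(b)),
                        metric = "hausdorff", threshold = 36)
  expect_equal(c(rep2$tp, rep2$fp, rep2$fn), c(1, 0, 0))
  expect_true(all(rep2$pairs$distance <= 36))
  expect_error(match_objects(object_set(list(), dim = c(5, 5)), labs),
               "empty reference|non-empty|must")
})

test_that("greedy matching solves a constructed 3x2 instance optimally", {
  H <- 40; W <- 80
  mk <- function(y, x) { m <- matrix(0L, H, W); m[y:(y+4), x:(x+4)] <- 1L; m }
  ref <- object_set(list(mk(5, 5), mk(5, 25), mk(25, 5)))
  pred <- object_set(list(mk(7, 6), mk(25, 7)), source = "predicted")
  rep <- match_objects(ref, pred, metric = "hausdorff", threshold = 30)
  D <- matrix(Inf, 3, 2)
  for (i in 1:3) for (j in 1:2)
    D[i, j] <- hausdorff(ref$coords[[i]], pred$coords[[j]])
  expect_equal(rep$tp, oracle_best_match_count(D, 30))
  expect_equal(rep$tp + rep$fn, 3)
  expect_equal(rep$tp + rep$fp, 2)
  # one-to-one
  expect_equal(anyDuplicated(rep$pairs$ref), 0)
  expect_equal(anyDuplicated(rep$pairs$pred), 0)
})

test_that("summaries aggregate rates per group", {
  labs <- matrix(0L, 20, 20); labs[3:8, 3:8] <- 1L
  ref <- object_set(labs)
  r1 <- match_objects(ref, labs, metric = "jaccard")
  s1 <- summarize_match_reports(list(r1))
  expect_equal(s1$tp_mean, 1); expect_equal(s1$tp_sd, 0)
  expect_equal(s1$tp_max, s1$tp_min)
  # two reports 0.6 / 0.8 -> mean 0.7 (recompute oracle by hand)
  r2 <- r1; r2$tp_rate <- 0.6; r2$fp_rate <- 0.1
  r3 <- r1; r3$tp_rate <- 0.8; r3$fp_rate <- 0.3
  s2 <- summarize_match_reports(list(r2, r3))
  expect_equal(s2$tp_mean, 0.7)
  expect_equal(s2$fp_mean, 0.2)
  expect_equal(s2$tp_sd, stats::sd(c(0.6, 0.8)))
  s3 <- summarize_match_reports(list(r2, r3), groups = c("benign",
                                                         "malignant"))
  expect_equal(nrow(s3), 2)
})
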