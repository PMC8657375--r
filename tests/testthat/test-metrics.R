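toy_masks <- function() {
  m <- array(0L, c(4, 4, 2)); gt <- array(0L, c(4, 4, 2))
  m[1:4, 1, 1] <- 1L                 # |M| = 4
  gt[2:4, 1, 1] <- 1L; gt[1:3, 2, 1] <- 1L # |GT| = 6, overlap = 3
  list(m = m, gt = gt)
}

test_that("precision, recall and Dice match hand counts on toy masks", {
  tm <- toy_masks()
  pr <- precision_recall(tm$m, tm$gt)
  expect_equal(pr[["precision"]], 0.75)
  expect_equal(pr[["recall"]], 0.5)
  expect_equal(dice(tm$m, tm$gt), 0.6)
  expect_equal(precision_recall(tm$gt, tm$gt), c(precision = 1, recall = 1))
  expect_equal(dice(tm$gt, tm$gt), 1)
  disj <- array(0L, c(4, 4, 2)); disj[4, 4, 2] <- 1L
  expect_equal(precision_recall(disj, tm$gt), c(precision = 0, recall = 0))
  expect_equal(dice(disj, tm$gt), 0)
})

test_that("degenerate inputs follow the documented conventions", {
  tm <- toy_masks()
  empty <- array(0L, dim(tm$gt))
  expect_error(precision_recall(tm$m, empty), "ground truth")
  pr <- precision_recall(empty, tm$gt)
  expect_equal(pr[["precision"]], 0) # pessimistic convention, flagged
  expect_true(isTRUE(attr(pr, "empty_prediction")))
  expect_error(dice(empty, empty), "undefined")
  expect_error(precision_recall(tm$m, array(0L, c(2, 2, 2))), "shape")
})

test_that("Dice is symmetric and equals the precision-recall harmonic mean", {
  set.seed(77)
  for (rep in 1:15) {
    m <- array(rbinom(128, 1, 0.4), c(8, 4, 4))
    gt <- array(rbinom(128, 1, 0.4), c(8, 4, 4))
    if (sum(gt) == 0 || sum(m) == 0) next
    expect_equal(dice(m, gt), dice(gt, m))
    pr <- precision_recall(m, gt)
    p <- pr[["precision"]]; r <- pr[["recall"]]
    if (p + r > 0) {
      expect_equal(dice(m, gt), 2 * p * r / (p + r), tolerance = 1e-12)
    }
  }
})

test_that("metrics are computed on the 3D reconstruction, not slice means", {
  # slice 1: perfect; slice 2: tiny GT missed entirely. The mean of the
  # per-slice Dice values differs from the 3D Dice.
  m <- array(0L, c(4, 4, 2)); gt <- array(0L, c(4, 4, 2))
  m[1:2, 1:2, 1] <- 1L; gt[1:2, 1:2, 1] <- 1L
  gt[1, 1, 2] <- 1L
  d3 <- dice(m, gt)
  expect_equal(d3, 2 * 4 / (4 + 5))
  slice_mean <- mean(c(1, 0)) # per-slice Dice values
  expect_false(isTRUE(all.equal(d3, slice_mean)))
})

test_that("PR curve handles perfect, inverted and random confidences", {
  gt <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  res <- pr_curve_auc(list(gt * 1.0), list(gt))
  expect_true(all(res$curve$precision == 1))
  expect_true(all(res$curve$recall == 1))
  expect_equal(res$auc, 1)
  res0 <- pr_curve_auc(list(1 - gt), list(gt))
  expect_true(all(res0$curve$precision == 0))
  expect_equal(res0$auc, 0)

  set.seed(88)
  f <- 0.3
  gts <- lapply(1:6, function(i) array(rbinom(4096, 1, f), c(16, 16, 16)))
  confs <- lapply(1:6, function(i) array(runif(4096), c(16, 16, 16)))
  res_r <- pr_curve_auc(confs, gts)
  # random scores: precision ~ GT fraction at every threshold (3 s.e.)
  for (i in seq_along(res_r$curve$threshold)) {
    t <- res_r$curve$threshold[i]
    n_sel <- 4096 * (1 - t) # expected selected voxels per case
    se <- sqrt(f * (1 - f) / n_sel) / sqrt(6)
    expect_lt(abs(res_r$curve$precision[i] - f), 3 * se + 0.01)
  }
  # higher thresholds shrink the mask: recall non-increasing
  expect_true(all(diff(res_r$curve$recall) <= 0))
  expect_error(pr_curve_auc(confs, gts, thresholds = c(0.5, 0.4)),
               "ascending")
})

test_that("detection-segmentation correlation handles the edge cases", {
  df <- data.frame(box_precision = c(0.5, 0.6, 0.7, 0.8),
                   box_recall = c(0.9, 0.8, 0.85, 0.95))
  df$seg_precision <- df$box_precision
  df$seg_recall <- df$box_recall
  df$seg_dice <- df$box_precision
  res <- detection_segmentation_correlation(df)
  expect_equal(res["box_precision", "seg_precision"], 1)
  expect_equal(res["box_recall", "seg_recall"], 1)

  set.seed(99)
  n <- 400
  ind <- data.frame(box_precision = runif(n), box_recall = runif(n),
                    seg_precision = runif(n), seg_recall = runif(n),
                    seg_dice = runif(n))
  res_i <- detection_segmentation_correlation(ind)
  expect_true(all(abs(res_i) < 3 / sqrt(n))) # ~0 within CI
  cst <- ind; cst$box_recall <- 0.5
  res_c <- detection_segmentation_correlation(cst)
  expect_true(all(is.na(res_c["box_recall", ]))) # undefined, not 0
  expect_error(detection_segmentation_correlation(data.frame(x = 1)),
               "columns")
})
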