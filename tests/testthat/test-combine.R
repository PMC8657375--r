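test_that("the disagreement set is exactly the label mismatch", {
  a <- array(0.9, c(4, 4, 2)); b <- array(0.9, c(4, 4, 2))
  expect_false(any(discr_set(a, b)))
  b2 <- array(0.1, c(4, 4, 2))
  expect_true(all(discr_set(a, b2)))
  # mixed toy grid, enumerated by hand
  a3 <- array(c(0.9, 0.2, 0.6, 0.4), c(2, 2, 1))
  b3 <- array(c(0.8, 0.7, 0.3, 0.1), c(2, 2, 1))
  expect_identical(as.vector(discr_set(a3, b3)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(discr_set(a, array(0, c(2, 2, 2))), "shape")
})

test_that("weight optimisation recovers boundary and symmetric optima", {
  # every DISCR voxel has GT = 1, FLAIR confident, T2w wrong: omega* = 1
  a <- array(0.9, c(3, 3, 2)); b <- array(0.1, c(3, 3, 2))
  gt <- array(1L, c(3, 3, 2))
  res <- optimize_weight(a, b, gt)
  expect_lt(abs(res$omega - 1), 0.02)
  # mirrored two-voxel problem: symmetry forces omega* = 0.5
  a2 <- array(c(0.9, 0.1), c(2, 1, 1)); b2 <- array(c(0.1, 0.9), c(2, 1, 1))
  gt2 <- array(c(1L, 1L), c(2, 1, 1))
  res2 <- optimize_weight(a2, b2, gt2)
  expect_lt(abs(res2$omega - 0.5), 0.02)
  # empty DISCR: 0.5 by convention
  res3 <- optimize_weight(a, a, gt)
  expect_equal(res3$omega, 0.5)
  expect_equal(res3$n_discr, 0L)
  expect_error(optimize_weight(array(1.5, c(2, 2, 1)),
                               array(0.1, c(2, 2, 1)),
                               array(1L, c(2, 2, 1))), "\\[0, 1\\]")
})

test_that("Brent's optimum agrees with a 101-point grid oracle", {
  grid_oracle <- function(a, b, gt) {
    d <- discr_set(a, b)
    ya <- a[d]; yb <- b[d]; yv <- gt[d]
    ws <- seq(0, 1, by = 0.01)
    obj <- vapply(ws, function(w) {
      p <- pmin(pmax(w * ya + (1 - w) * yb, 1e-7), 1 - 1e-7)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    }, numeric(1))
    ws[which.min(obj)]
  }
  set.seed(55)
  for (rep in 1:20) {
    a <- array(runif(60), c(5, 4, 3))
    b <- array(runif(60), c(5, 4, 3))
    gt <- array(rbinom(60, 1, 0.4), c(5, 4, 3))
    if (!any(discr_set(a, b))) next
    res <- optimize_weight(a, b, gt)
    expect_lte(abs(res$omega - grid_oracle(a, b, gt)), 0.02)
    # optimum no worse than either endpoint
    obj_at <- function(w) {
      d <- discr_set(a, b)
      p <- pmin(pmax(w * a[d] + (1 - w) * b[d], 1e-7), 1 - 1e-7)
      -mean(gt[d] * log(p) + (1 - gt[d]) * log(1 - p))
    }
    expect_lte(res$objective, min(obj_at(0), obj_at(1)) + 1e-8)
  }
})

test_that("confidence fusion is the stated weighted average", {
  a <- array(0.8, c(2, 2, 1)); b <- array(0.4, c(2, 2, 1))
  expect_equal(ensemble_confidences(a, b, 1), a)
  expect_equal(ensemble_confidences(a, b, 0), b)
  expect_equal(ensemble_confidences(a, b, 0.5)[1], 0.6)
  expect_error(ensemble_confidences(a, b, 1.2), "omega")
})

test_that("masking intersects and moves precision/recall as predicted", {
  shape <- c(4, 4, 2)
  seg <- array(0L, shape); gt <- array(0L, shape); box <- array(0L, shape)
  box[1:3, 1:3, 1] <- 1L
  gt[1:2, 1:2, 1] <- 1L            # 4 GT voxels, all inside the box
  seg[1:2, 1, 1] <- 1L; seg[2, 2, 1] <- 1L # 3 in-box hits, all true
  seg[4, 4, 2] <- 1L; seg[4, 3, 2] <- 1L   # 2 out-of-box false positives
  pr_before <- precision_recall(seg, gt)
  masked <- mask_segmentation(seg, box)
  pr_after <- precision_recall(masked, gt)
  expect_equal(pr_before[["precision"]], 0.6)
  expect_equal(pr_after[["precision"]], 1.0)    # FPs removed
  expect_equal(pr_after[["recall"]], pr_before[["recall"]]) # no TP lost
  # second toy: one GT voxel outside the box loses recall 1 -> 0.8
  gt2 <- array(0L, shape); gt2[1:2, 1:2, 1] <- 1L; gt2[4, 4, 2] <- 1L
  seg2 <- gt2
  pr2 <- precision_recall(mask_segmentation(seg2, box), gt2)
  expect_equal(pr2[["recall"]], 0.8)
  # containment and empty-box cases
  expect_identical(mask_segmentation(masked, box), masked)
  expect_equal(sum(mask_segmentation(seg, array(0L, shape))), 0)
})

test_that("masking never increases recall on any mask pair", {
  set.seed(66)
  for (rep in 1:25) {
    shape <- c(6, 6, 4)
    seg <- array(rbinom(144, 1, 0.3), shape)
    box <- array(rbinom(144, 1, 0.5), shape)
    gt <- array(rbinom(144, 1, 0.3), shape)
    if (sum(gt) == 0) next
    expect_lte(precision_recall(mask_segmentation(seg, box), gt)[["recall"]],
               precision_recall(seg, gt)[["recall"]])
  }
})

test_that("the pipeline fuses confidences before masking", {
  # fuse-then-mask differs from mask-then-fuse on this toy case, which
  # pins the implemented order
  box <- array(1L, c(2, 1, 1))
  conf_a <- array(c(0.9, 0.3), c(2, 1, 1))
  conf_b <- array(c(0.4, 0.8), c(2, 1, 1))
  res <- boxseg:::combine_and_mask(list(conf_a, conf_b), 0.5, box)
  expect_equal(as.vector(res$conf), c(0.65, 0.55))
  expect_equal(as.vector(res$seg), c(1L, 1L))
  # masking each thresholded modality first, then intersecting, would
  # keep only voxel 1; the fused route keeps both
  masked_each <- mask_segmentation(array(as.integer(conf_a > 0.5), dim(box)),
                                   box) &
    mask_segmentation(array(as.integer(conf_b > 0.5), dim(box)), box)
  expect_false(identical(as.integer(masked_each), as.integer(res$seg)))
})

test_that("single-modality cases run without ensembling", {
  res <- boxseg:::combine_and_mask(list(array(0.9, c(2, 2, 1))), 0.5,
                                   array(1L, c(2, 2, 1)))
  expect_equal(sum(res$seg), 4)
})
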