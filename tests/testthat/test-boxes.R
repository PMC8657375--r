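test_that("gt_box_from_mask returns the tightest half-open rectangle", {
  m <- matrix(0L, 12, 12)
  m[4:8, 3:6] <- 1L # rows 3..7, cols 2..5 in 0-based coordinates
  b <- gt_box_from_mask(m)
  expect_equal(as.numeric(b$rect), c(2, 3, 6, 8))
  expect_equal(b$confidence, 1)
  expect_null(gt_box_from_mask(matrix(0L, 5, 5)))
  m1 <- matrix(0L, 12, 12); m1[5, 10] <- 1L # pixel (y=4, x=9)
  expect_equal(as.numeric(gt_box_from_mask(m1)$rect), c(9, 4, 10, 5))
  expect_error(gt_box_from_mask(matrix(2, 3, 3)), "binary")
})

test_that("gt box covers every pixel and is minimal", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(0L, 16, 16)
    m[sample(256, sample(1:40, 1))] <- 1L
    b <- gt_box_from_mask(m)
    idx <- which(m > 0, arr.ind = TRUE)
    # recall 1: every pixel inside the box
    expect_true(all(idx[, 1] > b$rect[2] & idx[, 1] <= b$rect[4]))
    expect_true(all(idx[, 2] > b$rect[1] & idx[, 2] <= b$rect[3]))
    # minimality: each edge touches at least one pixel
    expect_true(any(idx[, 1] == b$rect[2] + 1))
    expect_true(any(idx[, 1] == b$rect[4]))
    expect_true(any(idx[, 2] == b$rect[1] + 1))
    expect_true(any(idx[, 2] == b$rect[3]))
  }
})

test_that("rasterisation fills rectangles and unions overlaps", {
  shape <- c(16L, 16L, 4L)
  b1 <- box_prediction(2, c(2, 3, 6, 8))
  expect_equal(sum(rasterize_boxes(list(b1), shape)),
               (6 - 2) * (8 - 3))
  expect_equal(sum(rasterize_boxes(list(), shape)), 0)
  b2 <- box_prediction(2, c(4, 5, 10, 12))
  both <- rasterize_boxes(list(b1, b2), shape)
  expect_true(all(both %in% c(0L, 1L)))
  expect_equal(sum(both), 4 * 5 + 6 * 7 - 2 * 3) # union, no double count
  # confidence map carries the max confidence
  cb <- rasterize_confidence(list(box_prediction(1, c(0, 0, 4, 4), 0.3),
                                  box_prediction(1, c(2, 2, 6, 6), 0.9)),
                             shape)
  expect_equal(cb[4, 4, 1], 0.9)
  expect_equal(cb[2, 2, 1], 0.3)
  expect_equal(max(cb[, , 2]), 0)
})

test_that("box_prediction validates its contract", {
  expect_error(box_prediction(1, c(5, 5, 5, 9)), "degenerate")
  expect_error(box_prediction(1, c(5, 5, 2, 9)), "degenerate")
  expect_error(box_prediction(1, c(0, 0, 4, 4), 1.2), "confidence")
})

test_that("axial regularisation fills gaps and removes short runs", {
  col_mask <- function(z_on, nz = 20) {
    m <- array(0L, c(2, 2, nz))
    m[1, 1, z_on] <- 1L
    m
  }
  # runs on slices 1..5 and 9..13 (gap of 3): closing merges them
  m <- col_mask(c(1:5, 9:13))
  out <- regularize_box_mask(m)
  expect_equal(which(out[1, 1, ] == 1), 1:13)
  # an isolated 2-slice run is removed by the opening
  out2 <- regularize_box_mask(col_mask(4:5))
  expect_equal(sum(out2), 0)
  # a 6-slice run survives unchanged
  out3 <- regularize_box_mask(col_mask(4:9))
  expect_equal(which(out3[1, 1, ] == 1), 4:9)
  # empty in, empty out
  expect_equal(sum(regularize_box_mask(array(0L, c(4, 4, 10)))), 0)
})

test_that("regularisation matches the run-length oracle on random columns", {
  set.seed(21)
  nz <- 40L
  n_cols <- 300L
  cols <- matrix(rbinom(n_cols * nz, 1, 0.35), n_cols, nz)
  m <- array(0L, c(n_cols, 1, nz))
  m[, 1, ] <- cols
  out <- regularize_box_mask(m)
  for (i in seq_len(n_cols)) {
    expect_identical(as.integer(out[i, 1, ]),
                     as.integer(runlength_close_open(cols[i, ])))
  }
})

test_that("regularisation is extensive-then-anti-extensive and idempotent", {
  set.seed(22)
  m <- array(rbinom(8 * 8 * 30, 1, 0.3), c(8, 8, 30))
  once <- regularize_box_mask(m)
  twice <- regularize_box_mask(once)
  expect_identical(twice, once) # idempotent on its own output
})

test_that("box-mask ensembling thresholds the weighted confidence", {
  shape <- c(8L, 8L, 2L)
  a <- rasterize_confidence(list(box_prediction(1, c(0, 0, 4, 4), 1)), shape)
  b <- rasterize_confidence(list(box_prediction(1, c(0, 0, 4, 4), 1)), shape)
  for (w in c(0, 0.3, 0.7, 1)) {
    expect_equal(sum(ensemble_box_masks(a, b, w)), 16)
  }
  empty <- array(0, shape)
  expect_equal(sum(ensemble_box_masks(a, empty, 0.4)), 0) # 0.4 < 0.5 drops
  expect_equal(sum(ensemble_box_masks(a, empty, 0.6)), 16)
  expect_identical(ensemble_box_masks(a, empty, 1),
                   array(as.integer(a > 0.5), shape))
  expect_error(ensemble_box_masks(a, array(0, c(4, 4, 2))), "shape")
})

test_that("detection failure flags tiny box masks and low GT recall", {
  brain <- array(1L, c(10, 10, 10))
  expect_true(detection_failed(array(0L, dim(brain)), brain)$failed)
  big <- array(0L, dim(brain)); big[1:10, 1:10, 1] <- 1L # 10% of brain
  expect_false(detection_failed(big, brain)$failed)
  gt <- array(0L, dim(brain)); gt[, , 5:6] <- 1L
  box <- array(0L, dim(brain)); box[1, 1:2, 5] <- 1L # recall 2/200 = 0.01
  res <- detection_failed(box, brain, min_frac = 1e-5, gt = gt)
  expect_false(res$failed)
  expect_equal(res$gt_recall, 0.01)
  expect_true(res$recall_failed) # below the 0.015 criterion
})

test_that("generic region box enlarges by the stated fraction per side", {
  shape <- c(40L, 40L, 40L)
  m <- generic_region_box(c(20, 20, 20), c(10, 10, 10), 0.5, shape)
  expect_equal(sum(m), 20^3) # 10 + 5 + 5 per axis
  m0 <- generic_region_box(c(20, 20, 20), c(10, 10, 10), 0, shape)
  expect_equal(sum(m0), 10^3)
  expect_warning(mc <- generic_region_box(c(2, 2, 2), c(10, 10, 10), 0.5,
                                          shape), "clip")
  expect_true(sum(mc) < 20^3 && sum(mc) > 0)
})

test_that("box JSON-lines serialisation round-trips and validates", {
  boxes <- list(box_prediction(1, c(2, 3, 6, 8), 0.9),
                box_prediction(5, c(0, 0, 4, 4), 0.25))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_boxes(boxes, path)
  back <- load_external_boxes(path)
  expect_equal(back, boxes)
  # malformed record names its line
  writeLines(c(readLines(path), '{"slice": 2, "x_min": 1}'), path)
  expect_error(load_external_boxes(path), "line 3")
  # negative-area box
  writeLines('{"slice":1,"x_min":5,"y_min":0,"x_max":2,"y_max":4,"confidence":0.5}',
             path)
  expect_error(load_external_boxes(path), "line 1")
  # out-of-range confidence
  writeLines('{"slice":1,"x_min":0,"y_min":0,"x_max":2,"y_max":4,"confidence":1.2}',
             path)
  expect_error(load_external_boxes(path), "line 1")
})
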