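test_that("config validation and build-time divisibility checks", {
  expect_error(seg_config(depth = 1), "depth")
  expect_error(seg_config(learning_rate = 0), "learning_rate")
  expect_silent(build_unet(seg_config(depth = 5, input_size = 64)))
  expect_error(build_unet(seg_config(depth = 5, input_size = 63)),
               "divisible")
  expect_error(
    train_segmenter(build_unet(seg_config(depth = 3, epochs = 1)),
                    list(matrix(0, 10, 10)), list(matrix(0, 10, 10))),
    "divisible")
})

test_that("same seed yields identical initial parameters", {
  a <- build_unet(seg_config(seed = 7))
  b <- build_unet(seg_config(seed = 7))
  expect_identical(a$params, b$params)
  c <- build_unet(seg_config(seed = 8))
  expect_false(identical(a$params, c$params))
})

test_that("UNet forbids box slices and BB-UNet requires them", {
  cfg <- seg_config(depth = 2, epochs = 1)
  sl <- list(matrix(0.5, 8, 8)); gt <- list(matrix(0L, 8, 8))
  expect_error(train_segmenter(build_unet(cfg), sl, gt,
                               gt_box_slices = gt), "box")
  expect_error(train_segmenter(build_bbunet(cfg), sl, gt), "box")
})

test_that("an empty box mask gates every BB-UNet skip to exactly zero", {
  set.seed(31)
  cfg <- seg_config(depth = 3, base_channels = 4, seed = 3)
  m <- build_bbunet(cfg)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  zero_box <- array(0, c(16, 16, 1, 1))
  fwd <- boxseg:::unet_forward(m$params, x, 3, box = zero_box,
                               keep_cache = TRUE)
  for (l in 1:2) {
    expect_true(all(fwd$cache$gate[[l]] == 0))
    expect_true(all(fwd$cache$skip[[l]] == 0))
  }
  # the output is therefore independent of the encoder skips: a second
  # input agreeing only on the bottleneck path cannot be constructed
  # directly, but zero gates make the gated skips identically zero, which
  # pins the independence by construction
  one_box <- array(1, c(16, 16, 1, 1))
  fwd1 <- boxseg:::unet_forward(m$params, x, 3, box = one_box,
                                keep_cache = TRUE)
  for (l in 1:2) {
    expect_gt(max(fwd1$cache$gate[[l]]), 0) # all-one box opens gates
  }
})

test_that("training overfits two slices and loss hits zero at y = yhat", {
  set.seed(32)
  spec <- easy_spec()
  cs <- generate_case(spec, 1)
  zs <- order(apply(cs$gt, 3, sum), decreasing = TRUE)[1:2]
  v <- minmax_normalize(cs$volumes$FLAIR)
  st <- extract_axial_slices(v)
  slices <- st$slices[zs]
  gts <- lapply(zs, function(k) cs$gt[, , k])
  cfg <- seg_config(depth = 3, base_channels = 4, epochs = 200,
                    batch_size = 2, seed = 5)
  m <- train_segmenter(build_unet(cfg), slices, gts, config = cfg)
  expect_lt(tail(m$losses, 1), head(m$losses, 1))
  conf <- boxseg:::softmax2(
    boxseg:::unet_forward(m$params, boxseg:::stack_slices_4d(slices),
                          3)$logits)[, , 2, ]
  pred <- array(as.integer(conf > 0.5), dim(conf))
  gt3 <- array(0L, dim(conf)); for (i in 1:2) gt3[, , i] <- gts[[i]]
  expect_gte(dice(pred, gt3), 0.95)
})

test_that("trained UNet reaches Dice >= 0.9 on easy held-out phantoms", {
  spec <- easy_spec()
  cases <- cached("easy_train", lapply(1:6, function(i) generate_case(spec, i)))
  td <- fixture_slices(cases)
  cfg <- seg_config(depth = 3, base_channels = 8, epochs = 10, seed = 1)
  m <- cached("easy_unet",
              train_segmenter(build_unet(cfg), td$slices, td$gts,
                              config = cfg))
  held <- lapply(101:103, function(i) generate_case(spec, i))
  ds <- vapply(held, function(cs) {
    conf <- infer_confidence(m, minmax_normalize(cs$volumes$FLAIR))
    dice(array(as.integer(conf > 0.5), dim(conf)), cs$gt)
  }, numeric(1))
  expect_gte(mean(ds), 0.9)
})

test_that("BB-UNet does better with faithful boxes than with wrong ones", {
  spec <- small_spec() # distractors + noise: box guidance carries signal
  cases <- cached("noisy_train", lapply(1:6, function(i) generate_case(spec, i)))
  td <- fixture_slices(cases)
  cfg <- seg_config(depth = 3, base_channels = 8, epochs = 15,
                    batch_size = 8, seed = 2)
  m <- cached("noisy_bbunet",
              train_segmenter(build_bbunet(cfg), td$slices, td$gts,
                              gt_box_slices = td$boxes, config = cfg))
  held <- lapply(11:13, function(i) generate_case(spec, i))
  dice_with_box <- function(cs, box_mask) {
    conf <- infer_confidence(m, minmax_normalize(cs$volumes$FLAIR),
                             box_mask = box_mask)
    dice(array(as.integer(conf > 0.5), dim(conf)), cs$gt)
  }
  d_gt <- vapply(held, function(cs) {
    shape <- dim(cs$gt)
    bm <- rasterize_boxes(Filter(Negate(is.null),
      lapply(seq_len(shape[3]), function(k)
        gt_box_from_mask(cs$gt[, , k], k))), shape)
    dice_with_box(cs, bm)
  }, numeric(1))
  d_wrong <- vapply(held, function(cs) {
    shape <- dim(cs$gt)
    # deliberately wrong box: a corner far from the lesion
    wrong <- rasterize_boxes(lapply(1:8, function(k)
      box_prediction(k, c(0, 0, 8, 8))), shape)
    dice_with_box(cs, wrong)
  }, numeric(1))
  expect_gt(mean(d_gt), mean(d_wrong))
})

test_that("inference is shape-preserving, bounded and deterministic", {
  spec <- easy_spec()
  cs <- generate_case(spec, 21)
  cfg <- seg_config(depth = 3, base_channels = 4, epochs = 1, seed = 1)
  td <- fixture_slices(list(cs))
  m <- train_segmenter(build_unet(cfg), td$slices, td$gts, config = cfg)
  v <- minmax_normalize(cs$volumes$FLAIR)
  c1 <- infer_confidence(m, v)
  c2 <- infer_confidence(m, v)
  expect_identical(dim(c1), dim(cs$gt))
  expect_true(all(c1 >= 0 & c1 <= 1))
  expect_identical(c1, c2)
  expect_identical(attr(c1, "modality"), "FLAIR")
  mb <- train_segmenter(build_bbunet(cfg), td$slices, td$gts,
                        gt_box_slices = td$boxes, config = cfg)
  expect_error(infer_confidence(mb, v), "box_mask")
  expect_error(infer_confidence(mb, v, box_mask = array(0L, c(8, 8, 2))),
               "shape")
})

test_that("training is deterministic given the seed", {
  spec <- easy_spec()
  cs <- generate_case(spec, 31)
  td <- fixture_slices(list(cs))
  cfg <- seg_config(depth = 2, base_channels = 4, epochs = 2, seed = 11)
  m1 <- train_segmenter(build_unet(cfg), td$slices, td$gts, config = cfg)
  m2 <- train_segmenter(build_unet(cfg), td$slices, td$gts, config = cfg)
  expect_identical(m1$params, m2$params)
})
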