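# Shared fixtures: small phantom specs and cached mini-cohorts. All
# fixtures are generated in code under fixed seeds; nothing is stored on
# disk.

# Small default-regime spec (distractors + noise), desk-test grid.
small_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(32, 32, 16), seed = seed)
}

# Easy-regime spec: high contrast, no noise, no distractors. Used to test
# that the architectures are sufficient when the task is easy.
easy_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(32, 32, 16),
    contrast = list(
      FLAIR = list(lesion_gain = 1.5, distractor_count = 0, noise_sd = 0),
      T2w = list(lesion_gain = 1.2, distractor_count = 0, noise_sd = 0)
    ),
    seed = seed
  )
}

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Training slices (image, gt, gt box mask) for one modality of a case list.
fixture_slices <- function(cases, modality = "FLAIR") {
  slices <- list(); gts <- list(); boxes <- list()
  for (cs in cases) {
    v <- minmax_normalize(cs$volumes[[modality]])
    st <- extract_axial_slices(v)
    for (k in seq_len(dim(cs$gt)[3])) {
      if (sum(cs$gt[, , k]) == 0) next
      slices[[length(slices) + 1]] <- st$slices[[k]]
      gts[[length(gts) + 1]] <- cs$gt[, , k]
      bx <- gt_box_from_mask(cs$gt[, , k], 1L) # single-slice raster frame
      boxes[[length(boxes) + 1]] <-
        rasterize_boxes(list(bx), c(dim(cs$gt)[1:2], 1))[, , 1]
    }
  }
  list(slices = slices, gts = gts, boxes = boxes)
}

# A small detector cohort trained once and reused across test files.
det_fixture <- function() {
  cached("det_fixture", {
    spec <- easy_spec()
    cases <- lapply(1:6, function(i) generate_case(spec, i))
    slices <- list(); boxes <- list()
    for (cs in cases) {
      v <- minmax_normalize(cs$volumes$FLAIR)
      st <- extract_axial_slices(v)
      for (k in seq_len(dim(cs$gt)[3])) {
        slices[[length(slices) + 1]] <- pad_and_channel(st$slices[[k]], 48)
        boxes[length(boxes) + 1] <- list(gt_box_from_mask(cs$gt[, , k], k))
      }
    }
    cfg <- detector_config(input_size = 48, epochs = 14, batch_size = 8,
                           pos_weight = 2, seed = 1)
    list(detector = train_detector(slices, boxes, cfg),
         slices = slices, boxes = boxes, cases = cases, cfg = cfg)
  })
}

# Brute-force run-length oracle for the 1D closing/opening along z:
# closing merges runs separated by a gap < k; opening removes runs
# shorter than k. Independent of the package's sliding-window morphology.
runlength_close_open <- function(col, k = 6L) {
  r <- rle(as.integer(col))
  # closing: flip internal zero-gaps shorter than k
  if (length(r$values) >= 3) {
    for (i in seq(2, length(r$values) - 1)) {
      if (r$values[i] == 0 && r$lengths[i] < k &&
          r$values[i - 1] == 1 && r$values[i + 1] == 1) {
        r$values[i] <- 1L
      }
    }
  }
  col2 <- inverse.rle(r)
  r2 <- rle(col2)
  r2$values[r2$values == 1 & r2$lengths < k] <- 0L
  inverse.rle(r2)
}
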