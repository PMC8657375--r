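#' Configuration for the desk-scale benchmark
#'
#' Problem sizes follow the study design at desk scale: a source-domain
#' training cohort, a 90/10-style validation split by case (never by
#' slice, to avoid leakage between slices of one volume), a held-out
#' source-domain test cohort and a domain-shifted test cohort.
#'
#' @param n_train,n_val,n_test,n_shifted cohort sizes.
#' @param spec the source-domain [phantom_spec()]; the shifted cohort uses
#'   [shift_domain()] of it.
#' @param seg_epochs,det_epochs training epochs for segmenters/detector.
#' @param depth,base_channels segmenter size (desk scale).
#' @param det_input detector input size after padding.
#' @param slices_per_case positive/negative axial slices sampled per
#'   training case for the segmenters (`c(pos, neg)`).
#' @param det_neg_per_case negative slices per case for detector training.
#' @param seed master seed; every stage derives its RNG from it.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_train = 40L, n_val = 8L, n_test = 10L,
                             n_shifted = 10L, spec = phantom_spec(),
                             seg_epochs = 6L, det_epochs = 8L, depth = 3L,
                             base_channels = 8L, det_input = 96L,
                             slices_per_case = c(5L, 3L),
                             det_neg_per_case = 8L, seed = 1L) {
  structure(list(n_train = n_train, n_val = n_val, n_test = n_test,
                 n_shifted = n_shifted, spec = spec,
                 seg_epochs = seg_epochs, det_epochs = det_epochs,
                 depth = depth, base_channels = base_channels,
                 det_input = det_input, slices_per_case = slices_per_case,
                 det_neg_per_case = det_neg_per_case,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# Enlarge a box rect by `margin` px per side, clipped to the slice.
pad_rect <- function(b, margin, shape2) {
  if (is.null(b) || margin == 0) return(b)
  r <- c(max(b$rect[1] - margin, 0), max(b$rect[2] - margin, 0),
         min(b$rect[3] + margin, shape2[2]), min(b$rect[4] + margin, shape2[1]))
  box_prediction(b$slice, r, b$confidence)
}

# Sample training slices (image, gt, gt-box-mask) from cases of one
# modality. GT boxes for BB-UNet training are dilated by `box_margin` px:
# a net trained with tight boxes (where most in-box voxels are tumour)
# learns to fill the box and over-segments inside the looser predicted
# boxes it sees at inference.
sample_training_slices <- function(cases, modality, n_pos, n_neg, seed,
                                   box_margin = 2) {
  with_seed(seed, {
    slices <- list(); gts <- list(); boxes <- list()
    for (cs in cases) {
      if (is.null(cs$volumes[[modality]])) next
      v <- minmax_normalize(cs$volumes[[modality]])
      st <- extract_axial_slices(v)
      zpos <- which(apply(cs$gt, 3, sum) > 0)
      zneg <- setdiff(seq_len(dim(cs$gt)[3]), zpos)
      zs <- c(sample(zpos, min(n_pos, length(zpos))),
              sample(zneg, min(n_neg, length(zneg))))
      for (k in zs) {
        slices[[length(slices) + 1]] <- st$slices[[k]]
        gts[[length(gts) + 1]] <- cs$gt[, , k]
        bx <- gt_box_from_mask(cs$gt[, , k], 1L) # single-slice raster frame
        bx <- pad_rect(bx, box_margin, dim(cs$gt)[1:2])
        boxes[[length(boxes) + 1]] <-
          rasterize_boxes(if (is.null(bx)) list() else list(bx),
                          c(dim(cs$gt)[1:2], 1))[, , 1]
      }
    }
    list(slices = slices, gts = gts, boxes = boxes)
  })
}

# Detector training data: padded 3-channel slices + GT boxes.
sample_detector_slices <- function(cases, modality, input_size, n_neg, seed) {
  with_seed(seed, {
    slices <- list(); boxes <- list()
    for (cs in cases) {
      if (is.null(cs$volumes[[modality]])) next
      v <- minmax_normalize(cs$volumes[[modality]])
      st <- extract_axial_slices(v)
      zpos <- which(apply(cs$gt, 3, sum) > 0)
      zneg <- setdiff(seq_len(dim(cs$gt)[3]), zpos)
      zs <- c(zpos, sample(zneg, min(n_neg, length(zneg))))
      for (k in zs) {
        slices[[length(slices) + 1]] <- pad_and_channel(st$slices[[k]],
                                                        input_size)
        boxes[length(boxes) + 1] <- list(gt_box_from_mask(cs$gt[, , k], k))
      }
    }
    list(slices = slices, boxes = boxes)
  })
}

# Predicted, regularised box confidence map for one case/modality.
predict_box_map <- function(det, case, modality) {
  vol <- minmax_normalize(case$volumes[[modality]])
  st <- extract_axial_slices(vol)
  padded <- lapply(st$slices, pad_and_channel, det$config$input_size)
  boxes <- detect_boxes(det, padded)
  regularize_box_mask(rasterize_confidence(boxes, dim(vol$data)))
}

# Ensembled (or single-modality) binary box mask from per-modality maps.
fuse_box_maps <- function(maps, omega) {
  if (length(maps) == 2L) {
    ensemble_box_masks(maps[[1]], maps[[2]], omega)
  } else {
    array(as.integer(as_vol_array(maps[[1]]) > 0), dim(as_vol_array(maps[[1]])))
  }
}

#' Run the desk-scale benchmark
#'
#' Trains a detector, a UNet and a BB-UNet per modality on the
#' source-domain cohort, optimises the box- and segmentation-ensembling
#' weights on the validation split, and evaluates UNet (unmasked), pYU,
#' BB-UNet with ground-truth boxes, BB-UNet with predicted boxes
#' (unmasked) and sYBBU on the held-out source-domain and shifted-domain
#' cohorts. Detection failures are flagged and reported separately, never
#' silently imputed.
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional directory for CSV reports.
#' @param verbose print stage progress.
#' @return list with `metrics` (per-case data.frame), `summary`
#'   (cohort-mean table), `omega` (optimised weights), `failures`,
#'   `correlation` (detection vs segmentation metrics on the source test
#'   cohort), and the trained `models`.
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config$spec
  spec$seed <- config$seed
  spec_shift <- shift_domain(spec)
  mods <- names(spec$contrast)

  say("generating cohorts (train %d, val %d, test %d, shifted %d)",
      config$n_train, config$n_val, config$n_test, config$n_shifted)
  train_cases <- lapply(seq_len(config$n_train), function(i)
    generate_case(spec, i))
  val_cases <- lapply(config$n_train + seq_len(config$n_val), function(i)
    generate_case(spec, i))
  test_cases <- lapply(1000L + seq_len(config$n_test), function(i)
    generate_case(spec, i))
  shift_cases <- lapply(2000L + seq_len(config$n_shifted), function(i)
    generate_case(spec_shift, i))

  detectors <- list(); unets <- list(); bbunets <- list()
  for (m in mods) {
    say("training detector [%s]", m)
    dd <- sample_detector_slices(train_cases, m, config$det_input,
                                 config$det_neg_per_case,
                                 seed = config$seed + 11)
    detectors[[m]] <- train_detector(
      dd$slices, dd$boxes,
      detector_config(input_size = config$det_input,
                      epochs = config$det_epochs, pos_weight = 2,
                      seed = config$seed + 21))
    say("training UNet [%s]", m)
    td <- sample_training_slices(train_cases, m, config$slices_per_case[1],
                                 config$slices_per_case[2],
                                 seed = config$seed + 31)
    scfg <- seg_config(depth = config$depth,
                       base_channels = config$base_channels,
                       epochs = config$seg_epochs, seed = config$seed + 41)
    unets[[m]] <- train_segmenter(build_unet(scfg), td$slices, td$gts,
                                  config = scfg)
    say("training BB-UNet [%s]", m)
    bcfg <- seg_config(depth = config$depth,
                       base_channels = config$base_channels,
                       epochs = config$seg_epochs, seed = config$seed + 51)
    bbunets[[m]] <- train_segmenter(build_bbunet(bcfg), td$slices, td$gts,
                                    gt_box_slices = td$boxes, config = bcfg)
  }

  say("optimising ensembling weights on the validation split")
  box_maps_val <- lapply(val_cases, function(cs)
    lapply(stats::setNames(mods, mods), function(m)
      predict_box_map(detectors[[m]], cs, m)))
  gt_val <- lapply(val_cases, `[[`, "gt")
  omega_box <- optimize_weight(lapply(box_maps_val, `[[`, 1),
                               lapply(box_maps_val, `[[`, 2), gt_val)$omega
  unet_conf_val <- lapply(val_cases, function(cs)
    lapply(stats::setNames(mods, mods), function(m)
      infer_confidence(unets[[m]], minmax_normalize(cs$volumes[[m]]))))
  omega_unet <- optimize_weight(lapply(unet_conf_val, `[[`, 1),
                                lapply(unet_conf_val, `[[`, 2), gt_val)$omega
  bb_conf_val <- lapply(seq_along(val_cases), function(i) {
    cs <- val_cases[[i]]
    bm <- fuse_box_maps(box_maps_val[[i]], omega_box)
    lapply(stats::setNames(mods, mods), function(m)
      infer_confidence(bbunets[[m]], minmax_normalize(cs$volumes[[m]]),
                       box_mask = bm))
  })
  omega_bb <- optimize_weight(lapply(bb_conf_val, `[[`, 1),
                              lapply(bb_conf_val, `[[`, 2), gt_val)$omega
  omega <- list(boxes = omega_box, unet = omega_unet, bbunet = omega_bb)
  say("omega: boxes %.3f, unet %.3f, bbunet %.3f",
      omega_box, omega_unet, omega_bb)

  evaluate_cohort <- function(cases, cohort) {
    rows <- list(); failures <- 0L
    for (i in seq_along(cases)) {
      cs <- cases[[i]]
      id <- sprintf("%s%03d", cohort, i)
      shape <- dim(cs$gt)
      box_maps <- lapply(stats::setNames(mods, mods), function(m)
        predict_box_map(detectors[[m]], cs, m))
      box_mask <- fuse_box_maps(box_maps, omega$boxes)
      flag <- detection_failed(box_mask, cs$brain_mask, gt = cs$gt)
      if (flag$failed) {
        failures <- failures + 1L
        rows[[length(rows) + 1]] <-
          data.frame(case_id = id, stage = "detection", tag = "failed",
                     precision = NA_real_, recall = NA_real_,
                     dice = NA_real_, stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1]] <-
        metrics_record(id, "detection", "ens_boxes", box_mask, cs$gt)

      gt_box_mask <- rasterize_boxes(Filter(Negate(is.null),
        lapply(seq_len(shape[3]), function(k)
          pad_rect(gt_box_from_mask(cs$gt[, , k], k), 2, shape[1:2]))),
        shape)

      unet_conf <- lapply(stats::setNames(mods, mods), function(m)
        infer_confidence(unets[[m]], minmax_normalize(cs$volumes[[m]])))
      res_pyu <- combine_and_mask(unet_conf, omega$unet, box_mask)
      rows[[length(rows) + 1]] <-
        metrics_record(id, "segmentation", "unet", res_pyu$seg_unmasked, cs$gt)
      rows[[length(rows) + 1]] <-
        metrics_record(id, "segmentation", "pyu", res_pyu$seg, cs$gt)

      bb_conf <- lapply(stats::setNames(mods, mods), function(m)
        infer_confidence(bbunets[[m]], minmax_normalize(cs$volumes[[m]]),
                         box_mask = box_mask))
      res_sybbu <- combine_and_mask(bb_conf, omega$bbunet, box_mask)
      rows[[length(rows) + 1]] <-
        metrics_record(id, "segmentation", "bbunet_pred_boxes",
                       res_sybbu$seg_unmasked, cs$gt)
      rows[[length(rows) + 1]] <-
        metrics_record(id, "segmentation", "sybbu", res_sybbu$seg, cs$gt)

      bbgt_conf <- lapply(stats::setNames(mods, mods), function(m)
        infer_confidence(bbunets[[m]], minmax_normalize(cs$volumes[[m]]),
                         box_mask = gt_box_mask))
      res_bbgt <- combine_and_mask(bbgt_conf, omega$bbunet, gt_box_mask)
      rows[[length(rows) + 1]] <-
        metrics_record(id, "segmentation", "bbunet_gt_boxes",
                       res_bbgt$seg_unmasked, cs$gt)
      rm(box_maps, unet_conf, bb_conf, bbgt_conf)
    }
    out <- do.call(rbind, rows)
    out$cohort <- cohort
    attr(out, "failures") <- failures
    out
  }

  say("evaluating held-out source-domain cohort")
  met_test <- evaluate_cohort(test_cases, "source_test")
  say("evaluating shifted-domain cohort")
  met_shift <- evaluate_cohort(shift_cases, "shifted_test")
  metrics <- rbind(met_test, met_shift)
  failures <- c(source_test = attr(met_test, "failures"),
                shifted_test = attr(met_shift, "failures"))

  summary <- stats::aggregate(
    metrics[!is.na(metrics$precision), c("precision", "recall", "dice")],
    by = list(cohort = metrics$cohort[!is.na(metrics$precision)],
              stage = metrics$stage[!is.na(metrics$precision)],
              tag = metrics$tag[!is.na(metrics$precision)]),
    FUN = mean)

  corr <- local({
    det_rows <- metrics[metrics$stage == "detection" &
                          metrics$cohort == "source_test" &
                          metrics$tag == "ens_boxes", ]
    seg_rows <- metrics[metrics$stage == "segmentation" &
                          metrics$cohort == "source_test" &
                          metrics$tag == "sybbu", ]
    shared <- intersect(det_rows$case_id, seg_rows$case_id)
    if (length(shared) >= 3) {
      detection_segmentation_correlation(data.frame(
        box_precision = det_rows$precision[match(shared, det_rows$case_id)],
        box_recall = det_rows$recall[match(shared, det_rows$case_id)],
        seg_precision = seg_rows$precision[match(shared, seg_rows$case_id)],
        seg_recall = seg_rows$recall[match(shared, seg_rows$case_id)],
        seg_dice = seg_rows$dice[match(shared, seg_rows$case_id)]))
    } else NULL
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics_per_case.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(data.frame(weight = names(unlist(omega)),
                         value = unlist(omega)),
              file.path(out_dir, "omega.csv"), row.names = FALSE)
  }

  list(metrics = metrics, summary = summary, omega = omega,
       failures = failures, correlation = corr,
       models = list(detectors = detectors, unets = unets,
                     bbunets = bbunets),
       config = config)
}
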