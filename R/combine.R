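#' Voxels where two modalities' labels disagree (DISCR)
#'
#' The support of the ensemble-weight objective: the weighted average can
#' only change the predicted label where the two modalities' thresholded
#' labels already differ, so the weight is optimised over exactly that set.
#'
#' @param conf_a,conf_b confidence volumes (same shape).
#' @param threshold label threshold (strictly above; default 0.5).
#' @return logical array marking the disagreement voxels.
#' @export
discr_set <- function(conf_a, conf_b, threshold = 0.5) {
  a <- as_vol_array(conf_a); b <- as_vol_array(conf_b)
  if (!identical(dim(a), dim(b))) stop("confidence volumes must share shape")
  (a > threshold) != (b > threshold)
}

#' Optimise the modality-ensembling weight
#'
#' Finds \eqn{\omega^* \in [0, 1]} minimising the cross-entropy of the
#' fused confidence \eqn{\hat y_v(\omega) = \omega\,\hat y_v^{A} +
#' (1-\omega)\,\hat y_v^{B}} against the ground truth, summed over the
#' disagreement voxels (DISCR) pooled across all validation cases. Solved
#' with Brent's bracketed scalar minimiser ([stats::optimize()]); the
#' endpoints 0 and 1 are checked explicitly. When DISCR is empty the
#' weight is immaterial (fusing cannot change any label) and 0.5 is
#' returned by convention.
#'
#' @param conf_a,conf_b lists (one element per validation case) of
#'   confidence volumes, or single volumes.
#' @param gt list of binary ground-truth arrays (or a single one).
#' @param threshold label threshold defining DISCR.
#' @return list with `omega` (the optimal weight), `objective` (its
#'   cross-entropy), and `n_discr` (pooled DISCR voxel count).
#' @export
optimize_weight <- function(conf_a, conf_b, gt, threshold = 0.5) {
  if (!is.list(conf_a)) conf_a <- list(conf_a)
  if (!is.list(conf_b)) conf_b <- list(conf_b)
  if (!is.list(gt)) gt <- list(gt)
  stopifnot(length(conf_a) == length(conf_b), length(conf_a) == length(gt))
  ya <- c(); yb <- c(); yv <- c()
  for (k in seq_along(conf_a)) {
    a <- as_vol_array(conf_a[[k]]); b <- as_vol_array(conf_b[[k]])
    if (min(a, b) < 0 || max(a, b) > 1) {
      stop("confidences must lie in [0, 1]")
    }
    d <- discr_set(a, b, threshold)
    if (!any(d)) next
    ya <- c(ya, a[d]); yb <- c(yb, b[d])
    yv <- c(yv, as_mask_array(gt[[k]], "gt")[d])
  }
  if (length(ya) == 0L) {
    return(list(omega = 0.5, objective = NA_real_, n_discr = 0L))
  }
  obj <- function(w) {
    p <- pmin(pmax(w * ya + (1 - w) * yb, 1e-7), 1 - 1e-7)
    -mean(yv * log(p) + (1 - yv) * log(1 - p))
  }
  br <- optimize(obj, c(0, 1))
  cand_w <- c(br$minimum, 0, 1)
  cand_f <- c(br$objective, obj(0), obj(1))
  best <- which.min(cand_f)
  list(omega = cand_w[best], objective = cand_f[best], n_discr = length(ya))
}

#' Fuse two confidence volumes by a weighted average
#'
#' @param conf_a,conf_b confidence volumes (same shape).
#' @param omega weight of `conf_a`, in `[0, 1]`.
#' @return numeric array `omega * conf_a + (1 - omega) * conf_b`.
#' @export
ensemble_confidences <- function(conf_a, conf_b, omega = 0.5) {
  a <- as_vol_array(conf_a); b <- as_vol_array(conf_b)
  if (!identical(dim(a), dim(b))) stop("confidence volumes must share shape")
  if (omega < 0 || omega > 1) stop("`omega` must lie in [0, 1]")
  out <- omega * a + (1 - omega) * b
  dim(out) <- dim(a)
  out
}

#' Mask a segmentation with a box mask
#'
#' Removes every segmented voxel outside the bounding-box mask
#' (SEG intersect BBOX). Masking can only remove voxels, so recall never
#' increases; when false positives concentrate outside the box — the
#' premise the box prior encodes — precision rises.
#'
#' @param seg binary 3D segmentation mask.
#' @param bbox binary 3D box mask.
#' @return binary integer array.
#' @export
mask_segmentation <- function(seg, bbox) {
  s <- as_mask_array(seg, "seg"); b <- as_mask_array(bbox, "bbox")
  if (!identical(dim(s), dim(b))) stop("masks must share shape")
  array(s * b, dim(s))
}

# Fuse per-modality confidence volumes (possibly one), threshold, mask.
# Ensembling is prior to masking: averaging does not commute with
# intersection, and the pipeline fuses soft confidences first.
combine_and_mask <- function(conf_list, omega, box_mask, threshold = 0.5) {
  conf <- if (length(conf_list) == 2L) {
    ensemble_confidences(conf_list[[1]], conf_list[[2]], omega)
  } else {
    as_vol_array(conf_list[[1]])
  }
  seg <- array(as.integer(conf > threshold), dim(conf))
  list(seg_unmasked = seg,
       seg = mask_segmentation(seg, box_mask),
       conf = conf)
}

#' Run the full detection-guided segmentation pipeline on one case
#'
#' Per available modality: normalise, slice, detect, rasterise the boxes
#' with their confidences, and regularise along the axial axis. With two
#' modalities the box maps are fused (weight `omega_boxes`) and thresholded
#' into one box mask; with one, that modality's regularised box support is
#' used. Then:
#' \describe{
#'   \item{pYU}{per-modality UNet confidences are fused (`omega_seg`),
#'     thresholded, and masked with the box mask;}
#'   \item{sYBBU}{per-modality BB-UNet confidences — computed with the box
#'     mask as additional input — are fused, thresholded, and masked with
#'     the same box mask.}
#' }
#' A failed detection (tiny box mask) yields an empty segmentation plus a
#' failure record rather than a silent fallback.
#'
#' @param case a `phantom_case` (or any list with `volumes`, `brain_mask`).
#' @param strategy `"pyu"` or `"sybbu"`.
#' @param detectors named list of trained detectors, one per modality.
#' @param segmenters named list of trained segmenters (UNets for pYU,
#'   BB-UNets for sYBBU), one per modality.
#' @param omega_boxes,omega_seg ensembling weights in `[0, 1]`.
#' @param mask_per_modality use each modality's own box mask for masking
#'   instead of the ensembled one (off by default: the ensembled mask both
#'   feeds BB-UNet and masks the output).
#' @param min_box_frac detection-failure threshold (see
#'   [detection_failed()]).
#' @return list with `seg` (final binary mask), `seg_unmasked`, `conf`,
#'   `box_mask`, `failed`, `boxes` (per modality), `confidences`
#'   (per modality).
#' @export
run_pipeline <- function(case, strategy = c("pyu", "sybbu"), detectors,
                         segmenters, omega_boxes = 0.5, omega_seg = 0.5,
                         mask_per_modality = FALSE, min_box_frac = 0.001) {
  strategy <- match.arg(strategy)
  mods <- names(case$volumes)
  if (length(mods) < 1L) stop("case has no modalities")
  shape <- dim(case$volumes[[mods[1]]]$data)

  conf_maps <- list(); box_lists <- list()
  for (m in mods) {
    det <- detectors[[m]] %||% detectors[[1]]
    vol <- minmax_normalize(case$volumes[[m]])
    st <- extract_axial_slices(vol)
    padded <- lapply(st$slices, pad_and_channel, det$config$input_size)
    boxes <- detect_boxes(det, padded)
    box_lists[[m]] <- boxes
    conf_maps[[m]] <- regularize_box_mask(rasterize_confidence(boxes, shape))
  }
  box_mask <- if (length(mods) == 2L) {
    ensemble_box_masks(conf_maps[[1]], conf_maps[[2]], omega_boxes)
  } else {
    array(as.integer(conf_maps[[1]] > 0), shape)
  }

  flag <- detection_failed(box_mask, case$brain_mask, min_frac = min_box_frac)
  if (flag$failed) {
    return(list(seg = array(0L, shape), seg_unmasked = array(0L, shape),
                conf = array(0, shape), box_mask = box_mask,
                failed = TRUE, boxes = box_lists, confidences = NULL))
  }

  confs <- list()
  for (m in mods) {
    seg_model <- segmenters[[m]] %||% segmenters[[1]]
    need_box <- seg_model$arch == "bbunet"
    if (strategy == "sybbu" && !need_box) {
      stop("sYBBU requires BB-UNet segmenters")
    }
    if (strategy == "pyu" && need_box) {
      stop("pYU requires plain UNet segmenters")
    }
    vol <- minmax_normalize(case$volumes[[m]])
    mod_mask <- if (mask_per_modality) {
      array(as.integer(conf_maps[[m]] > 0), shape)
    } else box_mask
    confs[[m]] <- if (need_box) {
      infer_confidence(seg_model, vol, box_mask = mod_mask)
    } else {
      infer_confidence(seg_model, vol)
    }
  }
  res <- combine_and_mask(confs, omega_seg, box_mask)
  list(seg = res$seg, seg_unmasked = res$seg_unmasked, conf = res$conf,
       box_mask = box_mask, failed = FALSE, boxes = box_lists,
       confidences = confs)
}
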