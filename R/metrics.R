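#' Voxel precision and recall of a predicted mask
#'
#' \deqn{Recall(M) = |M \cap GT| / |GT|, \quad
#'       Precision(M) = |M \cap GT| / |M|}
#' computed on 3D-reconstructed masks (never averaged over 2D slices). An
#' empty predicted mask has precision 0 by the pessimistic convention, with
#' attribute `"empty_prediction"` set.
#'
#' @param m binary predicted mask (segmentation or box mask).
#' @param gt binary ground-truth mask (must be nonempty).
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(m, gt) {
  mm <- as_mask_array(m, "m"); gg <- as_mask_array(gt, "gt")
  if (!identical(dim(mm), dim(gg))) stop("masks must share shape")
  n_gt <- sum(gg)
  if (n_gt == 0L) stop("empty ground truth: recall is undefined")
  inter <- sum(mm & gg)
  n_m <- sum(mm)
  out <- c(precision = if (n_m == 0L) 0 else inter / n_m,
           recall = inter / n_gt)
  if (n_m == 0L) attr(out, "empty_prediction") <- TRUE
  out
}

#' Dice overlap index
#'
#' \deqn{Dice(M) = 2 |M \cap GT| / (|M| + |GT|)}
#'
#' @inheritParams precision_recall
#' @param gt binary mask; `|M| + |GT|` must be positive.
#' @return the Dice index in `[0, 1]`.
#' @export
dice <- function(m, gt) {
  mm <- as_mask_array(m, "m"); gg <- as_mask_array(gt, "gt")
  if (!identical(dim(mm), dim(gg))) stop("masks must share shape")
  denom <- sum(mm) + sum(gg)
  if (denom == 0L) stop("both masks empty: Dice is undefined")
  2 * sum(mm & gg) / denom
}

#' Mean precision-recall curve and its AUC over confidence thresholds
#'
#' At each threshold, the confidence volumes are binarised (strictly above)
#' and the precision and recall are averaged across cases; the AUC
#' integrates mean precision over mean recall by the trapezoid rule after
#' sorting by recall, extending the lowest-recall precision as a rectangle
#' down to recall 0 (so a degenerate all-perfect curve has AUC 1 and an
#' all-wrong curve AUC 0).
#'
#' @param confs list of confidence volumes (one per case).
#' @param gts list of binary ground-truth arrays.
#' @param thresholds ascending thresholds in `(0, 1)`; default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @return list with `curve` (data.frame threshold/precision/recall) and
#'   `auc`.
#' @export
pr_curve_auc <- function(confs, gts, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (!is.list(confs)) confs <- list(confs)
  if (!is.list(gts)) gts <- list(gts)
  stopifnot(length(confs) == length(gts), length(confs) >= 1)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1)) {
    stop("`thresholds` must be ascending within (0, 1)")
  }
  pr <- sapply(thresholds, function(t) {
    ms <- mapply(function(cf, gt) {
      m <- array(as.integer(as_vol_array(cf) > t), dim(as_vol_array(cf)))
      precision_recall(m, gt)
    }, confs, gts)
    rowMeans(ms)
  })
  curve <- data.frame(threshold = thresholds,
                      precision = pr["precision", ],
                      recall = pr["recall", ])
  ord <- order(curve$recall, curve$precision)
  r <- curve$recall[ord]; p <- curve$precision[ord]
  auc <- p[1] * r[1]
  if (length(r) > 1) {
    auc <- auc + sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  list(curve = curve, auc = auc)
}

#' Correlation between detection and segmentation performance
#'
#' Pearson correlations between the per-case box-mask metrics (precision,
#' recall) and the per-case segmentation metrics (precision, recall, Dice).
#' A metric that is constant across cases yields `NA` (undefined), not 0.
#'
#' @param records data.frame with per-case columns `box_precision`,
#'   `box_recall`, `seg_precision`, `seg_recall`, `seg_dice`.
#' @return a 2 x 3 correlation matrix (box metrics x segmentation metrics).
#' @export
detection_segmentation_correlation <- function(records) {
  need <- c("box_precision", "box_recall", "seg_precision", "seg_recall",
            "seg_dice")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "))
  }
  box <- c("box_precision", "box_recall")
  seg <- c("seg_precision", "seg_recall", "seg_dice")
  out <- matrix(NA_real_, 2, 3, dimnames = list(box, seg))
  for (b in box) for (s in seg) {
    x <- records[[b]]; y <- records[[s]]
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      out[b, s] <- cor(x, y)
    }
  }
  out
}

# Per-case detection + segmentation metrics row (internal helper for the
# benchmark report).
metrics_record <- function(case_id, stage, tag, m, gt) {
  pr <- precision_recall(m, gt)
  data.frame(case_id = case_id, stage = stage, tag = tag,
             precision = pr[["precision"]], recall = pr[["recall"]],
             dice = if (sum(m) + sum(gt) > 0) dice(m, gt) else NA_real_,
             stringsAsFactors = FALSE)
}
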