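#' Per-slice bounding-box prediction
#'
#' Rectangles are `(x_min, y_min, x_max, y_max)` in 0-based half-open pixel
#' coordinates (x indexes columns, y indexes rows); `slice` is the 1-based
#' axial slice index.
#'
#' @param slice integer axial slice index (1-based).
#' @param rect numeric length-4 rectangle.
#' @param confidence detection confidence in `[0, 1]`.
#' @return an object of class `box_prediction`.
#' @export
box_prediction <- function(slice, rect, confidence = 1) {
  rect <- as.numeric(rect)
  if (length(rect) != 4L) stop("`rect` must have 4 elements")
  if (!(rect[1] < rect[3]) || !(rect[2] < rect[4])) {
    stop("degenerate rectangle: need x_min < x_max and y_min < y_max")
  }
  if (confidence < 0 || confidence > 1) {
    stop("`confidence` must lie in [0, 1]")
  }
  names(rect) <- c("x_min", "y_min", "x_max", "y_max")
  structure(list(slice = as.integer(slice), rect = rect,
                 confidence = as.numeric(confidence)),
            class = "box_prediction")
}

#' Tightest ground-truth box of a 2D mask
#'
#' Returns the smallest rectangle containing every true pixel of a binary
#' slice mask (confidence 1), or `NULL` for an empty slice.
#'
#' @param slice_mask binary 2D matrix.
#' @param slice axial slice index attached to the prediction.
#' @return a [box_prediction()] or `NULL`.
#' @export
gt_box_from_mask <- function(slice_mask, slice = 1L) {
  if (!is.matrix(slice_mask)) stop("`slice_mask` must be a 2D matrix")
  u <- unique(as.vector(slice_mask))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) stop("`slice_mask` must be binary")
  idx <- which(slice_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  box_prediction(slice,
                 c(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
                   max(idx[, 2]), max(idx[, 1])),
                 confidence = 1)
}

# Clip a rect to (rows, cols) slice bounds; NULL if empty.
clip_rect <- function(rect, shape2) {
  cl <- c(max(rect[1], 0), max(rect[2], 0),
          min(rect[3], shape2[2]), min(rect[4], shape2[1]))
  if (cl[1] >= cl[3] || cl[2] >= cl[4]) return(NULL)
  cl
}

#' Rasterise box predictions into a binary 3D box mask
#'
#' Each box fills its rectangle on its slice; multiple boxes on one slice
#' contribute their union. Boxes are clipped to the volume bounds.
#'
#' @param boxes list of [box_prediction()]s.
#' @param shape integer length-3 volume shape.
#' @return binary integer 3D array (a BBOX mask).
#' @export
rasterize_boxes <- function(boxes, shape) {
  m <- array(0L, shape)
  for (b in boxes) {
    if (is.null(b)) next
    if (b$slice < 1L || b$slice > shape[3]) next
    r <- clip_rect(b$rect, shape[1:2])
    if (is.null(r)) next
    m[(r[2] + 1):r[4], (r[1] + 1):r[3], b$slice] <- 1L
  }
  m
}

#' Rasterise box predictions into a per-voxel confidence map
#'
#' Voxels covered by a box carry that box's detection confidence (the
#' maximum when boxes overlap); voxels outside every box are 0. This is the
#' representation used for box-mask ensembling across modalities.
#'
#' @inheritParams rasterize_boxes
#' @return numeric 3D array with values in `[0, 1]`.
#' @export
rasterize_confidence <- function(boxes, shape) {
  m <- array(0, shape)
  for (b in boxes) {
    if (is.null(b)) next
    if (b$slice < 1L || b$slice > shape[3]) next
    r <- clip_rect(b$rect, shape[1:2])
    if (is.null(r)) next
    ii <- (r[2] + 1):r[4]; jj <- (r[1] + 1):r[3]
    m[ii, jj, b$slice] <- pmax(m[ii, jj, b$slice], b$confidence)
  }
  m
}

# 1D grey-scale dilation (max) / erosion (min) along the z axis with a
# length-`k` flat structuring element whose origin sits at index floor(k/2)
# (0-based). The max/min pair uses adjoint windows so closing is extensive
# and opening anti-extensive. Both operate on an already zero-padded
# domain: the padding must be shared across the whole closing/opening
# pipeline (dilation mass beyond the volume edge participates in the
# subsequent erosion), so the caller pads once and crops once.
z_dilate <- function(ext, k) {
  nc <- ncol(ext)
  out <- matrix(0, nrow(ext), nc)
  o <- k %/% 2
  for (d in (o - k + 1):o) { # window [i - (k-1-o), i + o]
    js <- seq_len(nc) + d
    ok <- js >= 1 & js <= nc
    out[, ok] <- pmax(out[, ok, drop = FALSE], ext[, js[ok], drop = FALSE])
  }
  out
}

z_erode <- function(ext, k) {
  nc <- ncol(ext)
  out <- matrix(Inf, nrow(ext), nc)
  o <- k %/% 2
  for (d in -o:(k - 1 - o)) { # adjoint window [i - o, i + (k-1-o)]
    js <- seq_len(nc) + d
    ok <- js >= 1 & js <= nc
    out[, ok] <- pmin(out[, ok, drop = FALSE], ext[, js[ok], drop = FALSE])
    out[, !ok] <- 0
  }
  out
}

#' Morphological regularisation of a box mask along the axial axis
#'
#' Per-slice detection gives no guarantee of axial continuity: the detector
#' may miss the tumour on some slices or fire on isolated ones. A closing
#' followed by an opening with a `(1, 1, k)` structuring element (default
#' `k = 6`) fills inter-slice gaps shorter than `k` and removes isolated
#' detections spanning fewer than `k` slices.
#'
#' The operator is grey-scale (running max/min), so it applies unchanged to
#' binary box masks and to confidence-carrying box maps; on binary input it
#' reduces exactly to binary closing-then-opening, and the support of the
#' grey-scale result equals the binary result on the input's support.
#'
#' @param box_mask binary or confidence-valued 3D array.
#' @param kernel structuring element length along z (default 6).
#' @return array of the same shape and kind.
#' @export
regularize_box_mask <- function(box_mask, kernel = 6L) {
  arr <- as_vol_array(box_mask)
  d <- dim(arr)
  m2 <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  pad <- matrix(0, nrow(m2), kernel)
  ext <- cbind(pad, m2, pad)
  closed <- z_erode(z_dilate(ext, kernel), kernel)
  opened <- z_dilate(z_erode(closed, kernel), kernel)
  out <- array(opened[, kernel + seq_len(d[3]), drop = FALSE], d)
  if (is.integer(arr) || all(arr %in% c(0, 1))) storage.mode(out) <- "integer"
  out
}

#' Ensemble two modalities' box-confidence maps into one box mask
#'
#' Voxelwise weighted average of the rasterised, confidence-carrying box
#' maps of the two modalities, thresholded at 0.5.
#'
#' @param conf_a,conf_b numeric 3D confidence maps (0 outside boxes).
#' @param omega weight of `conf_a`, in `[0, 1]`.
#' @return binary integer 3D array.
#' @export
ensemble_box_masks <- function(conf_a, conf_b, omega = 0.5) {
  a <- as_vol_array(conf_a); b <- as_vol_array(conf_b)
  if (!identical(dim(a), dim(b))) stop("confidence maps must share shape")
  if (omega < 0 || omega > 1) stop("`omega` must lie in [0, 1]")
  out <- array(as.integer(omega * a + (1 - omega) * b > 0.5), dim(a))
  out
}

#' Flag a failed detection
#'
#' The ground-truth-free surrogate flags a detection as failed when the box
#' mask covers less than `min_frac` of the brain (a tiny or empty box).
#' When the ground truth is supplied, the recall-based variant (box recall
#' below 0.015) is additionally reported.
#'
#' @param box_mask binary 3D box mask.
#' @param brain_mask binary 3D brain mask.
#' @param min_frac minimum box/brain volume fraction (default 0.001).
#' @param gt optional binary ground-truth mask.
#' @return list with `failed` (the surrogate flag), `box_frac`, and — when
#'   `gt` is given — `gt_recall` and `recall_failed`.
#' @export
detection_failed <- function(box_mask, brain_mask, min_frac = 0.001,
                             gt = NULL) {
  bm <- as_mask_array(box_mask, "box_mask")
  br <- as_mask_array(brain_mask, "brain_mask")
  if (!identical(dim(bm), dim(br))) stop("masks must share shape")
  frac <- sum(bm) / max(sum(br), 1L)
  res <- list(failed = frac < min_frac, box_frac = frac,
              gt_recall = NA_real_, recall_failed = NA)
  if (!is.null(gt)) {
    g <- as_mask_array(gt, "gt")
    if (!identical(dim(g), dim(bm))) stop("gt must share shape")
    rec <- sum(bm & g) / max(sum(g), 1L)
    res$gt_recall <- rec
    res$recall_failed <- rec < 0.015
  }
  res
}

#' Generic-region baseline box
#'
#' A fixed 3D box around a known anatomical region (the stand-in for a
#' template-derived pons box), enlarged by a fraction of the region size on
#' each side. Serves as the location-prior baseline that a learned detector
#' must beat on the shifted-domain cohort.
#'
#' @param region_center numeric length-3 region centre (voxel coordinates).
#' @param region_size numeric length-3 region extent in voxels.
#' @param enlargement fraction of the size added on each side (default 0.5).
#' @param shape integer length-3 volume shape.
#' @return binary integer 3D array; clipped to the volume with a warning if
#'   the enlarged box exceeds it.
#' @export
generic_region_box <- function(region_center, region_size, enlargement = 0.5,
                               shape) {
  ext <- region_size * (1 + 2 * enlargement)
  lo <- region_center - ext / 2
  hi <- region_center + ext / 2
  # voxel v occupies the half-open cell [v-1, v); keep cells overlapping
  # the continuous interval [lo, hi)
  lo_i <- floor(lo) + 1 # 1-based voxel range
  hi_i <- ceiling(hi)
  if (any(lo_i < 1) || any(hi_i > shape)) {
    warning("generic region box exceeds volume bounds; clipping")
  }
  lo_i <- pmax(lo_i, 1); hi_i <- pmin(hi_i, shape)
  if (any(lo_i > hi_i)) stop("generic region box lies outside the volume")
  m <- array(0L, shape)
  m[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3]] <- 1L
  m
}

#' Write box predictions as JSON lines
#'
#' One record per line: `{"slice": k, "x_min": ..., "y_min": ...,
#' "x_max": ..., "y_max": ..., "confidence": ...}` (slice 1-based, pixel
#' coordinates 0-based half-open).
#'
#' @param boxes list of [box_prediction()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  lines <- vapply(boxes, function(b) {
    jsonlite::toJSON(
      list(slice = b$slice, x_min = b$rect[[1]], y_min = b$rect[[2]],
           x_max = b$rect[[3]], y_max = b$rect[[4]],
           confidence = b$confidence),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
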