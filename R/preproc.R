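#' Percentile min-max normalisation
#'
#' Harmonises intensities by mapping the 5th percentile to 0 and the 95th
#' percentile to 1, capping out-of-range values:
#' \deqn{\hat v = \max(\min((v - p_{05}) / (p_{95} - p_{05}), 1), 0)}
#' Percentiles are computed over brain voxels only by default (the brain
#' mask when present, otherwise nonzero voxels): after skull-stripping, the
#' background zeros would otherwise dominate whole-volume percentiles.
#' Linear interpolation between order statistics (`stats::quantile` type 7)
#' is used.
#'
#' @param vol a [volume()] (or 3D array).
#' @param probs the two percentile levels, default `c(0.05, 0.95)`.
#' @param over `"brain"` (default) to compute percentiles over brain/nonzero
#'   voxels, `"all"` to use every voxel.
#' @return the normalised volume with values in `[0, 1]`; the percentiles
#'   used are attached as attribute `"norm_stats"`. A constant input yields
#'   an all-zero volume with a warning.
#' @export
minmax_normalize <- function(vol, probs = c(0.05, 0.95),
                             over = c("brain", "all")) {
  over <- match.arg(over)
  is_vol <- inherits(vol, "bs_volume")
  arr <- as_vol_array(vol)
  if (!all(is.finite(arr))) stop("volume must be finite")
  sel <- if (over == "brain") {
    if (is_vol && !is.null(vol$brain_mask)) arr[vol$brain_mask > 0] else arr[arr != 0]
  } else {
    as.vector(arr)
  }
  if (length(sel) == 0L) sel <- as.vector(arr)
  qs <- quantile(sel, probs = probs, names = FALSE, type = 7)
  p_lo <- qs[1]; p_hi <- qs[2]
  if (p_hi == p_lo) {
    warning("constant intensities (p95 == p05); returning an all-zero volume")
    out <- array(0, dim(arr))
  } else {
    out <- pmax(pmin((arr - p_lo) / (p_hi - p_lo), 1), 0)
    dim(out) <- dim(arr)
  }
  attr(out, "norm_stats") <- c(p_lo = p_lo, p_hi = p_hi)
  if (is_vol) {
    res <- vol
    res$data <- out
    attr(res, "norm_stats") <- attr(out, "norm_stats")
    attr(res$data, "norm_stats") <- NULL
    return(res)
  }
  out
}

#' Extract the axial slices of a volume
#'
#' Models are trained and run on 2D axial slices (the third array axis);
#' the extraction is lossless and inverted by [restack_slices()].
#'
#' @param vol a [volume()] or 3D array.
#' @return a `slice_stack`: list of 2D matrices plus the source shape.
#' @export
extract_axial_slices <- function(vol) {
  arr <- if (inherits(vol, "bs_volume")) vol$data else vol
  if (!is.array(arr) || length(dim(arr)) != 3L) {
    stop("expected a 3D volume; got ",
         if (is.array(arr)) paste0(length(dim(arr)), "D") else class(arr)[1])
  }
  d <- dim(arr)
  slices <- lapply(seq_len(d[3]), function(k) arr[, , k])
  structure(list(slices = slices, dim = d, origin = 1L),
            class = "slice_stack")
}

#' Restack axial slices into a 3D volume
#'
#' @param stack a `slice_stack` from [extract_axial_slices()], or a plain
#'   list of equally-shaped 2D matrices.
#' @return a 3D array.
#' @export
restack_slices <- function(stack) {
  slices <- if (inherits(stack, "slice_stack")) stack$slices else stack
  d2 <- dim(slices[[1]])
  arr <- array(0, c(d2, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  arr
}

#' Pad a slice and replicate it to three channels
#'
#' Prepares a 2D slice for the detector: centred zero padding to
#' `target_size`, then replication of the grey-scale image into three
#' identical channels (so that detectors pretrained on RGB images remain
#' drop-in compatible). The padding offsets are recorded so that box
#' coordinates predicted in the padded frame can be mapped back with
#' [unpad_box()].
#'
#' @param slice a 2D matrix.
#' @param target_size scalar or length-2 `(rows, cols)` target size.
#' @return a `(target, target, 3)` array with attribute `"pad"` recording
#'   `offset` (rows, cols added before the image), `size` and `target`.
#' @export
pad_and_channel <- function(slice, target_size) {
  if (!is.matrix(slice)) stop("`slice` must be a 2D matrix")
  tgt <- if (length(target_size) == 1L) rep(as.integer(target_size), 2) else
    as.integer(target_size)
  d <- dim(slice)
  if (any(d > tgt)) {
    stop(sprintf("slice (%dx%d) larger than target (%dx%d)",
                 d[1], d[2], tgt[1], tgt[2]))
  }
  off <- (tgt - d) %/% 2L
  padded <- matrix(0, tgt[1], tgt[2])
  padded[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- slice
  out <- array(0, c(tgt, 3L))
  for (ch in 1:3) out[, , ch] <- padded
  attr(out, "pad") <- list(offset = off, size = d, target = tgt)
  out
}

#' Map a box from the padded detector frame back to slice coordinates
#'
#' Rectangles are `(x_min, y_min, x_max, y_max)` in 0-based half-open pixel
#' coordinates, with x indexing columns and y indexing rows.
#'
#' @param rect numeric length-4 rectangle in the padded frame.
#' @param pad the `"pad"` attribute recorded by [pad_and_channel()].
#' @param clip clip the result to the slice bounds (default). An empty
#'   rectangle after clipping yields `NULL`.
#' @return the rectangle in slice coordinates (with the unclipped rectangle
#'   attached as attribute `"unclipped"`), or `NULL`.
#' @export
unpad_box <- function(rect, pad, clip = TRUE) {
  r <- as.numeric(rect)
  raw <- c(r[1] - pad$offset[2], r[2] - pad$offset[1],
           r[3] - pad$offset[2], r[4] - pad$offset[1])
  if (!clip) return(raw)
  cl <- c(max(raw[1], 0), max(raw[2], 0),
          min(raw[3], pad$size[2]), min(raw[4], pad$size[1]))
  if (cl[1] >= cl[3] || cl[2] >= cl[4]) return(NULL)
  names(cl) <- c("x_min", "y_min", "x_max", "y_max")
  attr(cl, "unclipped") <- raw
  cl
}
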