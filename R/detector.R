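#' Configuration for the built-in reference detector
#'
#' The detection stage is a pluggable contract — any source of per-slice
#' [box_prediction()]s will do (see [load_external_boxes()]). The built-in
#' reference detector honours the same contract with a small
#' fully-convolutional network: a conv encoder with two 2x2 poolings and a
#' 1x1 objectness head over a grid of 4x4-pixel cells. A slice's box is the
#' bounding rectangle of its above-threshold cells; its confidence is the
#' maximum cell probability. The default confidence threshold is
#' permissive (0.25): the box exists to hand the segmenter a region that
#' reliably contains the whole tumour, so recall is favoured over
#' precision.
#'
#' @param input_size padded slice size fed to the detector (divisible by 4).
#' @param confidence_threshold objectness threshold in `(0, 1]`;
#'   predictions require cell probability strictly above it.
#' @param max_boxes_per_slice boxes kept per slice (highest confidence
#'   first); the reference detector emits at most one object per connected
#'   cell component.
#' @param epochs,learning_rate,batch_size training hyper-parameters.
#' @param channels encoder channel widths (three stages).
#' @param pos_weight weight of positive cells in the objectness loss
#'   (positives are rare; upweighting speeds convergence).
#' @param seed RNG seed controlling initialisation and batch order.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(input_size = 96L, confidence_threshold = 0.25,
                            max_boxes_per_slice = 1L, epochs = 10L,
                            learning_rate = 1e-3, batch_size = 32L,
                            channels = c(8L, 16L, 32L), pos_weight = 3,
                            seed = 1L) {
  if (confidence_threshold <= 0 || confidence_threshold > 1) {
    stop("`confidence_threshold` must lie in (0, 1]")
  }
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (input_size %% 4L != 0L) stop("`input_size` must be divisible by 4")
  structure(list(input_size = as.integer(input_size),
                 confidence_threshold = confidence_threshold,
                 max_boxes_per_slice = as.integer(max_boxes_per_slice),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 channels = as.integer(channels),
                 pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "detector_config")
}

detector_init_params <- function(config) {
  ch <- config$channels
  list(c1_w = he_weights(3, 3, 3, ch[1]), c1_b = numeric(ch[1]),
       c2_w = he_weights(3, 3, ch[1], ch[2]), c2_b = numeric(ch[2]),
       c3_w = he_weights(3, 3, ch[2], ch[3]), c3_b = numeric(ch[3]),
       head_w = matrix(rnorm(ch[3], 0, sqrt(2 / ch[3])), ch[3], 1),
       head_b = numeric(1))
}

# Forward to the cell logit map: (S/4, S/4, 1, N).
detector_forward <- function(params, x, keep_cache = FALSE) {
  h1 <- relu(conv_fw(x, params$c1_w, params$c1_b))
  p1 <- pool_fw(h1)
  h2 <- relu(conv_fw(p1, params$c2_w, params$c2_b))
  p2 <- pool_fw(h2)
  h3 <- relu(conv_fw(p2, params$c3_w, params$c3_b))
  logits <- dense_fw(h3, params$head_w, params$head_b)
  if (keep_cache) {
    list(logits = logits,
         cache = list(x = x, h1 = h1, p1 = p1, h2 = h2, p2 = p2, h3 = h3))
  } else list(logits = logits)
}

detector_backward <- function(params, cache, glogits) {
  grads <- list()
  db <- dense_bw(cache$h3, params$head_w, glogits)
  grads$head_w <- db$gw; grads$head_b <- db$gb
  g3 <- relu_bw(db$gx, cache$h3)
  cb3 <- conv_bw(cache$p2, params$c3_w, g3)
  grads$c3_w <- cb3$gw; grads$c3_b <- cb3$gb
  g2p <- pool_bw(cb3$gx, cache$h2, cache$p2)
  g2 <- relu_bw(g2p, cache$h2)
  cb2 <- conv_bw(cache$p1, params$c2_w, g2)
  grads$c2_w <- cb2$gw; grads$c2_b <- cb2$gb
  g1p <- pool_bw(cb2$gx, cache$h1, cache$p1)
  g1 <- relu_bw(g1p, cache$h1)
  cb1 <- conv_bw(cache$x, params$c1_w, g1)
  grads$c1_w <- cb1$gw; grads$c1_b <- cb1$gb
  grads
}

# Cell label grid for one padded-frame rect (0-based half-open), cell = 4 px.
cell_labels <- function(rect, n_cells) {
  lab <- matrix(0, n_cells, n_cells)
  if (is.null(rect)) return(lab)
  cj <- (floor(rect[1] / 4) + 1):(ceiling(rect[3] / 4))
  ci <- (floor(rect[2] / 4) + 1):(ceiling(rect[4] / 4))
  cj <- cj[cj >= 1 & cj <= n_cells]; ci <- ci[ci >= 1 & ci <= n_cells]
  lab[ci, cj] <- 1
  lab
}

#' Train the reference detector
#'
#' Minimises a positively-weighted cell-objectness cross-entropy: a cell is
#' positive when its 4x4-pixel footprint intersects the slice's ground-truth
#' box. Slices without a box are explicit negatives (all cells 0).
#' Deterministic given `config$seed`.
#'
#' @param slices list of padded 3-channel slices from [pad_and_channel()].
#' @param gt_boxes list parallel to `slices`: a [box_prediction()] (in
#'   original slice coordinates) or `NULL` for negative slices.
#' @param config a [detector_config()].
#' @return an object of class `bs_detector` with fields `params`, `config`,
#'   `losses` (mean loss per epoch).
#' @export
train_detector <- function(slices, gt_boxes, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  if (length(slices) != length(gt_boxes)) {
    stop("`slices` and `gt_boxes` must have the same length")
  }
  n_pos <- sum(!vapply(gt_boxes, is.null, logical(1)))
  if (n_pos == 0L) stop("no positive slices: at least one ground-truth box is required")
  S <- config$input_size
  nc <- S %/% 4L
  xb <- array(0, c(S, S, 3, length(slices)))
  yb <- array(0, c(nc, nc, 1, length(slices)))
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    pad <- attr(sl, "pad")
    if (is.null(pad) || !identical(dim(sl)[1:2], c(S, S))) {
      stop("slices must be preprocessed with pad_and_channel() at the ",
           "detector input size")
    }
    xb[, , , i] <- sl
    b <- gt_boxes[[i]]
    if (!is.null(b)) {
      r <- b$rect + c(pad$offset[2], pad$offset[1], pad$offset[2], pad$offset[1])
      yb[, , 1, i] <- cell_labels(r, nc)
    }
  }
  with_seed(config$seed, {
    params <- detector_init_params(config)
    st <- adam_init(params)
    n <- length(slices)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        x <- xb[, , , idx, drop = FALSE]
        y <- yb[, , , idx, drop = FALSE]
        fwd <- detector_forward(params, x, keep_cache = TRUE)
        p <- sigmoid(fwd$logits)
        w <- 1 + (config$pos_weight - 1) * y
        sw <- sum(w)
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        loss <- -sum(w * (y * log(pc) + (1 - y) * log(1 - pc))) / sw
        g <- w * (p - y) / sw
        dim(g) <- dim(fwd$logits)
        grads <- detector_backward(params, fwd$cache, g)
        upd <- adam_step(params, grads, st, config$learning_rate)
        params <- upd$params; st <- upd$state
        tot <- tot + loss * length(idx)
      }
      losses[ep] <- tot / n
    }
    structure(list(params = params, config = config, losses = losses),
              class = "bs_detector")
  })
}

# 4-connected components of a logical matrix; returns an integer label matrix.
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- q[1] + dd[1]; nj <- q[2] + dd[2]
        if (ni >= 1 && ni <= nrow(m) && nj >= 1 && nj <= ncol(m) &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

#' Run the detector on padded slices
#'
#' @param detector a trained `bs_detector`.
#' @param slices list of padded 3-channel slices from [pad_and_channel()]
#'   (an error is raised for unpadded input); element `k` is axial slice `k`.
#' @return list of [box_prediction()]s (slices below the confidence
#'   threshold contribute none).
#' @export
detect_boxes <- function(detector, slices) {
  stopifnot(inherits(detector, "bs_detector"))
  config <- detector$config
  S <- config$input_size
  pads <- lapply(slices, attr, "pad")
  if (any(vapply(pads, is.null, logical(1)))) {
    stop("slices must be preprocessed with pad_and_channel()")
  }
  xb <- array(0, c(S, S, 3, length(slices)))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]])[1:2], c(S, S))) {
      stop("slice size does not match the detector input size")
    }
    xb[, , , i] <- slices[[i]]
  }
  pmap <- sigmoid(detector_forward(detector$params, xb)$logits)
  out <- list()
  for (k in seq_along(slices)) {
    pm <- pmap[, , 1, k]
    on <- pm > config$confidence_threshold
    if (!any(on)) next
    lab <- label_components(on)
    comps <- seq_len(max(lab))
    confs <- vapply(comps, function(cc) max(pm[lab == cc]), numeric(1))
    keep <- comps[order(confs, decreasing = TRUE)]
    keep <- head(keep, config$max_boxes_per_slice)
    for (cc in keep) {
      idx <- which(lab == cc, arr.ind = TRUE)
      # cells are 4x4 px; cell (i, j) covers rows/cols (4(i-1)+1)..4i
      rect_pad <- c((min(idx[, 2]) - 1) * 4, (min(idx[, 1]) - 1) * 4,
                    max(idx[, 2]) * 4, max(idx[, 1]) * 4)
      # de-quantisation: a cell is positive as soon as the object touches
      # it, so the cell hull over-covers by (cell-1)/2 px per side in
      # expectation; shrink accordingly (never below 1 px extent)
      sh <- 1.5
      if (rect_pad[3] - rect_pad[1] > 2 * sh + 1) {
        rect_pad[1] <- rect_pad[1] + sh; rect_pad[3] <- rect_pad[3] - sh
      }
      if (rect_pad[4] - rect_pad[2] > 2 * sh + 1) {
        rect_pad[2] <- rect_pad[2] + sh; rect_pad[4] <- rect_pad[4] - sh
      }
      r <- unpad_box(rect_pad, pads[[k]])
      if (is.null(r)) next
      out[[length(out) + 1]] <- box_prediction(k, r, max(pm[lab == cc]))
    }
  }
  out
}

#' Load externally produced box predictions
#'
#' Reads a JSON-lines file with one record per line (`slice`, `x_min`,
#' `y_min`, `x_max`, `y_max`, `confidence`), validating each record. This
#' is the drop-in point for a full-scale external detector.
#'
#' @param path JSON-lines file.
#' @param slice_shape optional `(rows, cols)`; when given, rectangles are
#'   clipped to the slice bounds.
#' @return list of [box_prediction()]s.
#' @export
load_external_boxes <- function(path, slice_shape = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    need <- c("slice", "x_min", "y_min", "x_max", "y_max", "confidence")
    if (is.null(rec) || !all(need %in% names(rec))) {
      stop("malformed box record at line ", i, " of ", path)
    }
    rect <- c(rec$x_min, rec$y_min, rec$x_max, rec$y_max)
    if (!is.null(slice_shape)) {
      rect <- clip_rect(rect, slice_shape)
      if (is.null(rect)) stop("box at line ", i, " lies outside the slice")
    }
    b <- tryCatch(box_prediction(rec$slice, rect, rec$confidence),
                  error = function(e) {
                    stop("invalid box at line ", i, " of ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    out[[i]] <- b
  }
  out
}
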