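#' Configuration for the UNet / BB-UNet segmenters
#'
#' Defaults follow the published training recipe (100 epochs, initial
#' learning rate 0.001, Adam, 5 levels per path, no data augmentation);
#' desk-scale runs pass smaller `epochs`/`base_channels`/`depth`.
#'
#' @param depth number of levels per path (>= 2; default 5).
#' @param base_channels channels at the first level, doubled per level.
#' @param epochs training epochs (default 100).
#' @param learning_rate Adam initial learning rate (default 0.001).
#' @param batch_size slices per training batch.
#' @param threshold confidence threshold for labelling a voxel tumoral
#'   (strictly above; default 0.5).
#' @param input_size optional slice size; when given, divisibility by
#'   `2^(depth-1)` is checked at build time (it is always checked at use).
#' @param seed RNG seed controlling initialisation and batch order.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(depth = 5L, base_channels = 8L, epochs = 100L,
                       learning_rate = 1e-3, batch_size = 16L,
                       threshold = 0.5, input_size = NULL, seed = 1L) {
  if (depth < 2) stop("`depth` must be >= 2")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (epochs < 1) stop("`epochs` must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), threshold = threshold,
                 input_size = input_size, seed = as.integer(seed)),
            class = "seg_config")
}

check_divisible <- function(size, depth) {
  div <- 2^(depth - 1)
  if (any(size %% div != 0)) {
    stop(sprintf("input size %s not divisible by 2^(depth-1) = %d",
                 paste(size, collapse = "x"), div))
  }
}

build_segmenter <- function(config, arch) {
  stopifnot(inherits(config, "seg_config"))
  if (!is.null(config$input_size)) {
    check_divisible(config$input_size, config$depth)
  }
  params <- with_seed(config$seed,
                      unet_init_params(config$depth, config$base_channels,
                                       with_box_path = (arch == "bbunet")))
  structure(list(arch = arch, params = params, config = config,
                 losses = numeric(0)),
            class = "bs_segmenter")
}

#' Build a UNet segmenter
#'
#' Encoder-decoder with `depth` levels per path: stacked 3x3 convolutions
#' with ReLU activations and 2x2 max-pooling on the way down, transposed
#' convolutions on the way up, and skip connections between each encoding
#' level and its symmetric decoding level. The final layer is a 2-channel
#' soft-max (background, tumour).
#'
#' @param config a [seg_config()].
#' @return an untrained `bs_segmenter`.
#' @export
build_unet <- function(config = seg_config()) build_segmenter(config, "unet")

#' Build a BB-UNet segmenter
#'
#' A UNet plus a bounding-box path parallel to the encoder: the binary box
#' mask follows transformations similar to the image (per level:
#' downsampling, then a bias-free 3x3 convolution squashed to `[0, 1]`),
#' and each skip connection is gated by element-wise multiplication with
#' the encoded box before the decoder consumes it. Because the box path is
#' bias-free with a zero-preserving squashing, an all-zero box mask gates
#' every skip to exactly zero.
#'
#' @inheritParams build_unet
#' @return an untrained `bs_segmenter`.
#' @export
build_bbunet <- function(config = seg_config()) build_segmenter(config, "bbunet")

#' @export
print.bs_segmenter <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<bs_segmenter> %s  depth %d  base %d  %d parameters  %s\n",
              toupper(x$arch), x$config$depth, x$config$base_channels, np,
              if (length(x$losses)) "trained" else "untrained"))
  invisible(x)
}

stack_slices_4d <- function(slices) {
  d <- dim(slices[[1]])
  x <- array(0, c(d[1], d[2], 1, length(slices)))
  for (i in seq_along(slices)) x[, , 1, i] <- slices[[i]]
  x
}

#' Train a segmenter
#'
#' Minimises the voxel-averaged binary cross-entropy
#' \deqn{-[y \log \hat y + (1 - y)\log(1 - \hat y)]}
#' of the soft-max tumour confidence against the ground truth, with Adam
#' and no data augmentation. BB-UNet training requires per-slice
#' ground-truth box masks (`gt_box_slices`); UNet training forbids them.
#' Deterministic given `config$seed`.
#'
#' @param model an untrained (or previously trained) `bs_segmenter`.
#' @param slices list of normalised 2D image slices.
#' @param gt_slices list of binary ground-truth slices.
#' @param gt_box_slices list of binary box-mask slices (BB-UNet only).
#' @param config optional [seg_config()] overriding the model's.
#' @return the trained `bs_segmenter` (field `losses` holds the per-epoch
#'   mean training loss).
#' @export
train_segmenter <- function(model, slices, gt_slices, gt_box_slices = NULL,
                            config = NULL) {
  stopifnot(inherits(model, "bs_segmenter"))
  config <- config %||% model$config
  if (model$arch == "bbunet" && is.null(gt_box_slices)) {
    stop("BB-UNet training requires `gt_box_slices`")
  }
  if (model$arch == "unet" && !is.null(gt_box_slices)) {
    stop("UNet takes no box input; drop `gt_box_slices`")
  }
  if (length(slices) != length(gt_slices)) {
    stop("`slices` and `gt_slices` must have the same length")
  }
  check_divisible(dim(slices[[1]]), config$depth)
  xb <- stack_slices_4d(slices)
  yb <- stack_slices_4d(gt_slices)
  bb <- if (model$arch == "bbunet") stack_slices_4d(gt_box_slices) else NULL
  with_seed(config$seed, {
    params <- model$params
    st <- adam_init(params)
    n <- length(slices)
    losses <- numeric(config$epochs)
    use_box <- model$arch == "bbunet"
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        x <- xb[, , , idx, drop = FALSE]
        y <- yb[, , , idx, drop = FALSE]
        bx <- if (use_box) bb[, , , idx, drop = FALSE] else NULL
        fwd <- unet_forward(params, x, config$depth, box = bx,
                            keep_cache = TRUE)
        ce <- softmax_ce(fwd$logits, y)
        if (!is.finite(ce$loss)) {
          stop("NaN loss at epoch ", ep, "; reduce the learning rate")
        }
        grads <- unet_backward(params, fwd$cache, ce$grad, config$depth,
                               use_box)
        upd <- adam_step(params, grads, st, config$learning_rate)
        params <- upd$params; st <- upd$state
        tot <- tot + ce$loss * length(idx)
      }
      losses[ep] <- tot / n
    }
    model$params <- params
    model$losses <- c(model$losses, losses)
    model$config <- config
    model
  })
}

#' Infer a confidence volume
#'
#' Runs per-slice forward passes over a volume and restacks the soft-max
#' tumour confidences into a 3D confidence volume in `[0, 1]`. BB-UNet
#' requires a 3D box mask (typically predicted, regularised and — with two
#' modalities — ensembled); UNet ignores box input.
#'
#' @param model a trained `bs_segmenter`.
#' @param vol a [volume()], 3D array or `slice_stack` of normalised
#'   intensities.
#' @param box_mask binary 3D array (BB-UNet only; must match the volume
#'   shape).
#' @param batch_size slices per forward batch.
#' @return numeric 3D array of per-voxel tumour confidences, with the
#'   modality tag preserved as attribute `"modality"` when available.
#' @export
infer_confidence <- function(model, vol, box_mask = NULL, batch_size = 32L) {
  stopifnot(inherits(model, "bs_segmenter"))
  arr <- if (inherits(vol, "slice_stack")) restack_slices(vol) else as_vol_array(vol)
  d <- dim(arr)
  check_divisible(d[1:2], model$config$depth)
  use_box <- model$arch == "bbunet"
  if (use_box) {
    if (is.null(box_mask)) stop("BB-UNet inference requires `box_mask`")
    bm <- as_vol_array(box_mask)
    if (!identical(dim(bm), d)) stop("`box_mask` shape must match the volume")
  }
  conf <- array(0, d)
  for (start in seq(1, d[3], batch_size)) {
    ks <- start:min(start + batch_size - 1, d[3])
    x <- array(arr[, , ks], c(d[1], d[2], 1, length(ks)))
    x <- aperm(x, c(1, 2, 3, 4))
    bx <- if (use_box) array(bm[, , ks], c(d[1], d[2], 1, length(ks))) else NULL
    fwd <- unet_forward(model$params, x, model$config$depth, box = bx)
    p <- softmax2(fwd$logits)[, , 2, ]
    conf[, , ks] <- p
  }
  if (inherits(vol, "bs_volume")) attr(conf, "modality") <- vol$modality
  conf
}
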