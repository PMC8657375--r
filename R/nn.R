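# Minimal convolutional-network engine backing the detector and the
# UNet / BB-UNet segmenters. Batches are (H, W, C, N) arrays. 3x3 same
# convolutions run through compiled im2col+GEMM kernels; pooling, transposed
# convolution, 1x1 heads, activations and Adam are vectorised R.

conv_fw <- function(x, w, b) .conv3x3_fw(x, w, b)
conv_bw <- function(x, w, gy) .conv3x3_bw(x, w, gy)

relu <- function(x) {
  y <- pmax(x, 0); dim(y) <- dim(x); y
}
relu_bw <- function(gy, y) {
  g <- gy * (y > 0); dim(g) <- dim(gy); g
}

# 2x2 max pooling (stride 2). Returns the pooled array; the backward pass
# recomputes the argmax from (x, y), routing ties to the first window
# position so gradients are never duplicated.
pool_fw <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  y <- pmax(x[io, jo, , , drop = FALSE], x[io + 1, jo, , , drop = FALSE],
            x[io, jo + 1, , , drop = FALSE], x[io + 1, jo + 1, , , drop = FALSE])
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  y
}

pool_bw <- function(gy, x, y) {
  d <- dim(x)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  g <- array(0, d)
  taken <- array(FALSE, dim(y))
  for (pos in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    sub <- x[io + pos[1], jo + pos[2], , , drop = FALSE]
    dim(sub) <- dim(y)
    hit <- (sub == y) & !taken
    g[io + pos[1], jo + pos[2], , ] <- gy * hit
    taken <- taken | hit
  }
  g
}

# Transposed 2x2 stride-2 convolution: upsamples (H, W, Ci, N) to
# (2H, 2W, Co, N). Weights are (2, 2, Ci, Co).
upconv_mat <- function(w) {
  dw <- dim(w)
  matrix(aperm(w, c(3, 1, 2, 4)), nrow = dw[3]) # Ci x (4*Co), (ki,kj,co) cols
}

upconv_fw <- function(x, w, b) {
  d <- dim(x); dw <- dim(w); co <- dw[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]) # (H*W*N) x Ci
  yf <- xm %*% upconv_mat(w)                          # (H*W*N) x (4*Co)
  dim(yf) <- c(d[1], d[2], d[4], 2, 2, co)
  y <- array(0, c(2 * d[1], 2 * d[2], co, d[4]))
  for (ki in 1:2) for (kj in 1:2) {
    blk <- yf[, , , ki, kj, , drop = TRUE]
    dim(blk) <- c(d[1], d[2], d[4], co)
    y[seq(ki, 2 * d[1], 2), seq(kj, 2 * d[2], 2), , ] <- aperm(blk, c(1, 2, 4, 3))
  }
  y + rep(rep(b, each = 4 * d[1] * d[2]), d[4])
}

upconv_bw <- function(x, w, gy) {
  d <- dim(x); dw <- dim(w); co <- dw[4]
  gyf <- array(0, c(d[1], d[2], d[4], 2, 2, co))
  for (ki in 1:2) for (kj in 1:2) {
    blk <- gy[seq(ki, 2 * d[1], 2), seq(kj, 2 * d[2], 2), , , drop = FALSE]
    gyf[, , , ki, kj, ] <- aperm(blk, c(1, 2, 4, 3))
  }
  gym <- matrix(gyf, ncol = 4 * co)                  # (H*W*N) x (4*Co)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  gwm <- crossprod(xm, gym)                          # Ci x (4*Co)
  gw <- aperm(array(gwm, c(d[3], 2, 2, co)), c(2, 3, 1, 4))
  gxm <- gym %*% t(upconv_mat(w))
  gx <- aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  gb <- colSums(matrix(colSums(gym), nrow = 4))
  list(gx = gx, gw = gw, gb = gb)
}

# 1x1 convolution (per-pixel dense layer): w is Ci x Co.
dense_fw <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  ym <- sweep(xm %*% w, 2, b, `+`)
  aperm(array(ym, c(d[1], d[2], d[4], ncol(w))), c(1, 2, 4, 3))
}

dense_bw <- function(x, w, gy) {
  d <- dim(x); co <- ncol(w)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = co)
  list(gx = aperm(array(gym %*% t(w), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
       gw = crossprod(xm, gym),
       gb = colSums(gym))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp01_hard <- function(x) {
  y <- pmin(pmax(x, 0), 1); dim(y) <- dim(x); y
}

he_weights <- function(k1, k2, ci, co) {
  array(rnorm(k1 * k2 * ci * co, 0, sqrt(2 / (k1 * k2 * ci))),
        c(k1, k2, ci, co))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- Softmax cross-entropy (2-channel) -------------------------------------

# logits: (H, W, 2, N); y: (H, W, 1, N) binary tumour labels.
# Channel 1 = background, channel 2 = tumour. Log arguments are clamped to
# [1e-7, 1 - 1e-7] so the objective stays finite at saturated confidences.
softmax2 <- function(logits) {
  d <- dim(logits)
  dlt <- logits[, , 2, , drop = FALSE] - logits[, , 1, , drop = FALSE]
  p1 <- sigmoid(dlt)
  p <- array(0, d)
  p[, , 1, ] <- 1 - p1
  p[, , 2, ] <- p1
  p
}

softmax_ce <- function(logits, y) {
  p <- softmax2(logits)
  p1 <- p[, , 2, , drop = FALSE]
  pc <- pmin(pmax(p1, 1e-7), 1 - 1e-7)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  nvox <- length(y)
  g <- array(0, dim(logits))
  g[, , 1, ] <- (p[, , 1, ] - (1 - y[, , 1, ])) / nvox
  g[, , 2, ] <- (p[, , 2, ] - y[, , 1, ]) / nvox
  list(loss = loss, grad = g, p1 = p1)
}

# ---- UNet / BB-UNet --------------------------------------------------------

# Channel plan: level l has base * 2^(l-1) channels; depth D means D levels
# (D-1 encoder levels with skips + bottleneck).
unet_channels <- function(depth, base) base * 2^(seq_len(depth) - 1)

unet_init_params <- function(depth, base, in_ch = 1L, n_class = 2L,
                             with_box_path = FALSE) {
  ch <- unet_channels(depth, base)
  p <- list()
  cin <- in_ch
  for (l in seq_len(depth)) {
    p[[sprintf("enc%d_w1", l)]] <- he_weights(3, 3, cin, ch[l])
    p[[sprintf("enc%d_b1", l)]] <- numeric(ch[l])
    p[[sprintf("enc%d_w2", l)]] <- he_weights(3, 3, ch[l], ch[l])
    p[[sprintf("enc%d_b2", l)]] <- numeric(ch[l])
    cin <- ch[l]
  }
  for (l in seq_len(depth - 1)) {
    p[[sprintf("up%d_w", l)]] <- he_weights(2, 2, ch[l + 1], ch[l])
    p[[sprintf("up%d_b", l)]] <- numeric(ch[l])
    p[[sprintf("dec%d_w1", l)]] <- he_weights(3, 3, 2 * ch[l], ch[l])
    p[[sprintf("dec%d_b1", l)]] <- numeric(ch[l])
    p[[sprintf("dec%d_w2", l)]] <- he_weights(3, 3, ch[l], ch[l])
    p[[sprintf("dec%d_b2", l)]] <- numeric(ch[l])
    if (with_box_path) {
      # bias-free by construction: an all-zero box mask must gate every
      # skip connection to exactly zero. Weights start positive with a
      # per-channel sum near (but below) 1, so the initial gate is close
      # to a pass-through inside the box: training starts from a UNet
      # restricted to the box, and reliance on the box can only be
      # learned, never blocked by a closed random gate.
      p[[sprintf("box%d_w", l)]] <- array(runif(9 * ch[l], 0.06, 0.13),
                                          c(3, 3, 1, ch[l]))
    }
  }
  p[["out_w"]] <- matrix(rnorm(ch[1] * n_class, 0, sqrt(2 / ch[1])),
                         ch[1], n_class)
  p[["out_b"]] <- numeric(n_class)
  p
}

# Forward pass. x: (H, W, 1, N); box: (H, W, 1, N) binary or NULL.
# Returns list(logits, cache) when keep_cache, else list(logits).
unet_forward <- function(params, x, depth, box = NULL, keep_cache = FALSE) {
  d <- dim(x)
  div <- 2^(depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("input size %dx%d not divisible by 2^(depth-1) = %d",
                 d[1], d[2], div))
  }
  cache <- list(enc_in = list(), enc_h1 = list(), enc_h2 = list(),
                up_out = list(), cat = list(), dec_h1 = list(),
                dec_h2 = list(), box_in = list(), gate_u = list(),
                gate = list(), skip = list())
  use_box <- !is.null(box)
  if (use_box) {
    bx <- box
    for (l in seq_len(depth - 1)) {
      cache$box_in[[l]] <- bx
      bx <- pool_fw(bx)
    }
  }
  a <- x
  for (l in seq_len(depth)) {
    cache$enc_in[[l]] <- a
    h1 <- relu(conv_fw(a, params[[sprintf("enc%d_w1", l)]],
                       params[[sprintf("enc%d_b1", l)]]))
    h2 <- relu(conv_fw(h1, params[[sprintf("enc%d_w2", l)]],
                       params[[sprintf("enc%d_b2", l)]]))
    cache$enc_h1[[l]] <- h1
    cache$enc_h2[[l]] <- h2
    if (l < depth) a <- pool_fw(h2)
  }
  dtop <- cache$enc_h2[[depth]]
  for (l in rev(seq_len(depth - 1))) {
    u <- upconv_fw(dtop, params[[sprintf("up%d_w", l)]],
                   params[[sprintf("up%d_b", l)]])
    cache$up_out[[l]] <- u
    skip <- cache$enc_h2[[l]]
    if (use_box) {
      gu <- conv_fw(cache$box_in[[l]], params[[sprintf("box%d_w", l)]],
                    numeric(dim(params[[sprintf("box%d_w", l)]])[4]))
      g <- clamp01_hard(gu)
      cache$gate_u[[l]] <- gu
      cache$gate[[l]] <- g
      skip <- skip * g
    }
    cache$skip[[l]] <- skip
    dcat <- abind4(skip, u)
    cache$cat[[l]] <- dcat
    h1 <- relu(conv_fw(dcat, params[[sprintf("dec%d_w1", l)]],
                       params[[sprintf("dec%d_b1", l)]]))
    h2 <- relu(conv_fw(h1, params[[sprintf("dec%d_w2", l)]],
                       params[[sprintf("dec%d_b2", l)]]))
    cache$dec_h1[[l]] <- h1
    cache$dec_h2[[l]] <- h2
    dtop <- h2
  }
  logits <- dense_fw(dtop, params$out_w, params$out_b)
  if (keep_cache) list(logits = logits, cache = cache) else list(logits = logits)
}

# Concatenate two (H, W, C, N) arrays along the channel axis.
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backward pass; returns gradients for every parameter.
unet_backward <- function(params, cache, glogits, depth, use_box) {
  grads <- list()
  dtop <- cache$dec_h2[[1]] %||% cache$enc_h2[[depth]]
  db <- dense_bw(dtop, params$out_w, glogits)
  grads$out_w <- db$gw; grads$out_b <- db$gb
  gd <- db$gx
  g_skip_up <- vector("list", depth) # grad flowing into enc_h2[[l]] via pooling
  for (l in seq_len(depth - 1)) {
    # decoder level l (processed top-down in backprop order)
    g2 <- relu_bw(gd, cache$dec_h2[[l]])
    cb2 <- conv_bw(cache$dec_h1[[l]], params[[sprintf("dec%d_w2", l)]], g2)
    grads[[sprintf("dec%d_w2", l)]] <- cb2$gw
    grads[[sprintf("dec%d_b2", l)]] <- cb2$gb
    g1 <- relu_bw(cb2$gx, cache$dec_h1[[l]])
    cb1 <- conv_bw(cache$cat[[l]], params[[sprintf("dec%d_w1", l)]], g1)
    grads[[sprintf("dec%d_w1", l)]] <- cb1$gw
    grads[[sprintf("dec%d_b1", l)]] <- cb1$gb
    csk <- dim(cache$skip[[l]])[3]
    gskip <- cb1$gx[, , seq_len(csk), , drop = FALSE]
    gu <- cb1$gx[, , csk + seq_len(dim(cache$up_out[[l]])[3]), , drop = FALSE]
    if (use_box) {
      g_enc <- gskip * cache$gate[[l]]
      g_gate <- gskip * cache$enc_h2[[l]]
      mask <- (cache$gate_u[[l]] > 0) & (cache$gate_u[[l]] < 1)
      g_gu <- g_gate * mask
      dim(g_gu) <- dim(g_gate)
      cbb <- conv_bw(cache$box_in[[l]], params[[sprintf("box%d_w", l)]], g_gu)
      grads[[sprintf("box%d_w", l)]] <- cbb$gw
      gskip <- g_enc
    }
    g_skip_up[[l]] <- gskip
    ub <- upconv_bw(if (l == depth - 1) cache$enc_h2[[depth]] else
      cache$dec_h2[[l + 1]], params[[sprintf("up%d_w", l)]], gu)
    grads[[sprintf("up%d_w", l)]] <- ub$gw
    grads[[sprintf("up%d_b", l)]] <- ub$gb
    gd <- ub$gx # gradient w.r.t. the level-(l+1) decoder output
  }
  # encoder, from the bottleneck up
  g_h2 <- gd # at this point gd is the grad w.r.t. enc_h2[[depth]]
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      gpool <- pool_bw(g_pooled, cache$enc_h2[[l]],
                       cache$enc_in[[l + 1]])
      g_h2 <- gpool + g_skip_up[[l]]
    }
    g2 <- relu_bw(g_h2, cache$enc_h2[[l]])
    cb2 <- conv_bw(cache$enc_h1[[l]], params[[sprintf("enc%d_w2", l)]], g2)
    grads[[sprintf("enc%d_w2", l)]] <- cb2$gw
    grads[[sprintf("enc%d_b2", l)]] <- cb2$gb
    g1 <- relu_bw(cb2$gx, cache$enc_h1[[l]])
    cb1 <- conv_bw(cache$enc_in[[l]], params[[sprintf("enc%d_w1", l)]], g1)
    grads[[sprintf("enc%d_w1", l)]] <- cb1$gw
    grads[[sprintf("enc%d_b1", l)]] <- cb1$gb
    g_pooled <- cb1$gx # grad w.r.t. enc_in[[l]] = pooled enc_h2[[l-1]]
  }
  grads
}
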