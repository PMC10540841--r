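# U-net for binary segmentation: classic encoder-decoder with skip
# connections (two 3x3 same-padding convs + ReLU per level, 2x2 max pooling,
# 2x2-stride-2 transposed-convolution upsampling, 1x1 sigmoid output head).
# Forward/backward run through the package's compiled im2col kernels; the
# optimizer is RMSProp (gradient normalised by a running RMS, with momentum
# and weight decay), the loss binary cross-entropy on the sigmoid output.

unet_channels <- function(base, depth) base * 2^(seq_len(depth + 1) - 1)

he_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# Parameter list keyed by layer name; 3x3 kernels are (9*Cin) x Cout,
# transposed-conv kernels (4*Cin) x Cout, the output head a Cin x 1 matrix.
unet_init <- function(in_channels = 1, base_channels = 16, depth = 4,
                      seed = 1L) {
  set.seed(as.integer(seed))
  ch <- unet_channels(base_channels, depth)
  p <- list()
  cin <- in_channels
  for (l in seq_len(depth)) {
    p[[sprintf("enc%d.c1.w", l)]] <- he_mat(9 * cin, ch[l], 9 * cin)
    p[[sprintf("enc%d.c1.b", l)]] <- numeric(ch[l])
    p[[sprintf("enc%d.c2.w", l)]] <- he_mat(9 * ch[l], ch[l], 9 * ch[l])
    p[[sprintf("enc%d.c2.b", l)]] <- numeric(ch[l])
    cin <- ch[l]
  }
  p[["bot.c1.w"]] <- he_mat(9 * ch[depth], ch[depth + 1], 9 * ch[depth])
  p[["bot.c1.b"]] <- numeric(ch[depth + 1])
  p[["bot.c2.w"]] <- he_mat(9 * ch[depth + 1], ch[depth + 1], 9 * ch[depth + 1])
  p[["bot.c2.b"]] <- numeric(ch[depth + 1])
  for (l in rev(seq_len(depth))) {
    cup <- ch[l + 1]
    p[[sprintf("dec%d.up.w", l)]] <- he_mat(4 * cup, ch[l], 4 * cup)
    p[[sprintf("dec%d.up.b", l)]] <- numeric(ch[l])
    p[[sprintf("dec%d.c1.w", l)]] <- he_mat(9 * 2 * ch[l], ch[l], 9 * 2 * ch[l])
    p[[sprintf("dec%d.c1.b", l)]] <- numeric(ch[l])
    p[[sprintf("dec%d.c2.w", l)]] <- he_mat(9 * ch[l], ch[l], 9 * ch[l])
    p[[sprintf("dec%d.c2.b", l)]] <- numeric(ch[l])
  }
  p[["out.w"]] <- he_mat(ch[1], 1, ch[1])
  # bias the output head toward the background prior so early optimisation
  # steps refine features instead of learning the class imbalance
  p[["out.b"]] <- -2
  p
}

conv_relu_fwd <- function(x, w, b) {
  a <- .conv3_fwd(x, w, b)
  a[a < 0] <- 0
  a
}

concat_c <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# Forward pass; input H and W must be divisible by 2^depth. Returns the
# logit raster (H x W matrix) plus the activation cache for the backward pass.
unet_forward <- function(params, x, depth) {
  cache <- list()
  cur <- x
  for (l in seq_len(depth)) {
    a1 <- conv_relu_fwd(cur, params[[sprintf("enc%d.c1.w", l)]],
                        params[[sprintf("enc%d.c1.b", l)]])
    a2 <- conv_relu_fwd(a1, params[[sprintf("enc%d.c2.w", l)]],
                        params[[sprintf("enc%d.c2.b", l)]])
    pl <- .maxpool2_fwd(a2)
    cache[[sprintf("e%d", l)]] <- list(in1 = cur, a1 = a1, a2 = a2,
                                       idx = pl$idx)
    cur <- pl$y
  }
  b1 <- conv_relu_fwd(cur, params[["bot.c1.w"]], params[["bot.c1.b"]])
  b2 <- conv_relu_fwd(b1, params[["bot.c2.w"]], params[["bot.c2.b"]])
  cache$bot <- list(in1 = cur, a1 = b1, a2 = b2)
  cur <- b2
  for (l in rev(seq_len(depth))) {
    up <- .upconv2_fwd(cur, params[[sprintf("dec%d.up.w", l)]],
                       params[[sprintf("dec%d.up.b", l)]])
    cat_in <- concat_c(cache[[sprintf("e%d", l)]]$a2, up)
    a1 <- conv_relu_fwd(cat_in, params[[sprintf("dec%d.c1.w", l)]],
                        params[[sprintf("dec%d.c1.b", l)]])
    a2 <- conv_relu_fwd(a1, params[[sprintf("dec%d.c2.w", l)]],
                        params[[sprintf("dec%d.c2.b", l)]])
    cache[[sprintf("d%d", l)]] <- list(up_in = cur, cat_in = cat_in,
                                       a1 = a1, a2 = a2)
    cur <- a2
  }
  hw <- dim(cur)[1] * dim(cur)[2]
  xm <- matrix(cur, hw, dim(cur)[3])
  logits <- matrix(xm %*% params[["out.w"]] + params[["out.b"]],
                   dim(cur)[1], dim(cur)[2])
  cache$head_in <- cur
  list(logits = logits, cache = cache)
}

conv_relu_bwd <- function(xin, w, act, gact) {
  gz <- gact
  gz[act <= 0] <- 0
  .conv3_bwd(xin, w, gz)
}

# Backward pass from d(loss)/d(logits); gradients keyed like the params.
unet_backward <- function(params, cache, dlogits, depth) {
  g <- list()
  head_in <- cache$head_in
  hw <- dim(head_in)[1] * dim(head_in)[2]
  xm <- matrix(head_in, hw, dim(head_in)[3])
  dl <- as.vector(dlogits)
  g[["out.w"]] <- crossprod(xm, dl)
  g[["out.b"]] <- sum(dl)
  gcur <- array(as.vector(outer(dl, as.vector(params[["out.w"]]))),
                dim(head_in))
  gskips <- list()
  # decoder, shallowest (last applied) first
  for (l in seq_len(depth)) {
    d <- cache[[sprintf("d%d", l)]]
    b2 <- conv_relu_bwd(d$a1, params[[sprintf("dec%d.c2.w", l)]], d$a2, gcur)
    g[[sprintf("dec%d.c2.w", l)]] <- b2$gw
    g[[sprintf("dec%d.c2.b", l)]] <- b2$gb
    b1 <- conv_relu_bwd(d$cat_in, params[[sprintf("dec%d.c1.w", l)]], d$a1,
                        b2$gx)
    g[[sprintf("dec%d.c1.w", l)]] <- b1$gw
    g[[sprintf("dec%d.c1.b", l)]] <- b1$gb
    nsk <- dim(d$cat_in)[3] / 2  # skip and upsampled halves are equal width
    gskips[[l]] <- b1$gx[, , seq_len(nsk), drop = FALSE]
    gup <- b1$gx[, , nsk + seq_len(nsk), drop = FALSE]
    bu <- .upconv2_bwd(d$up_in, params[[sprintf("dec%d.up.w", l)]], gup)
    g[[sprintf("dec%d.up.w", l)]] <- bu$gw
    g[[sprintf("dec%d.up.b", l)]] <- bu$gb
    gcur <- bu$gx  # gradient w.r.t. decoder level (l+1) output / bottleneck
  }
  bo <- cache$bot
  b2 <- conv_relu_bwd(bo$a1, params[["bot.c2.w"]], bo$a2, gcur)
  g[["bot.c2.w"]] <- b2$gw; g[["bot.c2.b"]] <- b2$gb
  b1 <- conv_relu_bwd(bo$in1, params[["bot.c1.w"]], bo$a1, b2$gx)
  g[["bot.c1.w"]] <- b1$gw; g[["bot.c1.b"]] <- b1$gb
  gcur <- b1$gx
  # encoder, deepest first
  for (l in rev(seq_len(depth))) {
    e <- cache[[sprintf("e%d", l)]]
    ga2 <- .maxpool2_bwd(e$idx, gcur, dim(e$a2)[1], dim(e$a2)[2]) +
      gskips[[l]]
    b2 <- conv_relu_bwd(e$a1, params[[sprintf("enc%d.c2.w", l)]], e$a2, ga2)
    g[[sprintf("enc%d.c2.w", l)]] <- b2$gw
    g[[sprintf("enc%d.c2.b", l)]] <- b2$gb
    b1 <- conv_relu_bwd(e$in1, params[[sprintf("enc%d.c1.w", l)]], e$a1,
                        b2$gx)
    g[[sprintf("enc%d.c1.w", l)]] <- b1$gw
    g[[sprintf("enc%d.c1.b", l)]] <- b1$gb
    gcur <- b1$gx
  }
  g
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean binary cross-entropy on logits plus its gradient.
bce_with_logits <- function(logits, target) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - target) / length(target))
}

# One RMSProp step (running mean-square normalisation, momentum buffer,
# decoupled-as-in-classic weight decay added to the raw gradient).
rmsprop_step <- function(params, grads, state, lr, alpha = 0.99,
                         eps = 1e-8, weight_decay = 0, momentum = 0) {
  for (k in names(params)) {
    gr <- grads[[k]] + weight_decay * params[[k]]
    state$sq[[k]] <- alpha * state$sq[[k]] + (1 - alpha) * gr^2
    upd <- gr / (sqrt(state$sq[[k]]) + eps)
    if (momentum > 0) {
      state$buf[[k]] <- momentum * state$buf[[k]] + upd
      upd <- state$buf[[k]]
    }
    params[[k]] <- params[[k]] - lr * upd
  }
  list(params = params, state = state)
}
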