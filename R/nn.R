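# Minimal feed-forward engine: dense / ReLU / 1-D convolution / max-pooling /
# residual blocks with analytic gradients and an Adam optimizer, enough to
# train every model family under one shared protocol. Activation tensors are
# laid out [length, batch, channels]; flat activations are [batch, features].
# Gradients are verified against numerical differentiation in the test suite.

nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = matrix(0, n_in, n_out), b = numeric(n_out))
}

nn_relu <- function() list(type = "relu")

nn_conv <- function(k, in_ch, out_ch, pad = 0) {
  list(type = "conv", k = k, in_ch = in_ch, out_ch = out_ch, pad = pad,
       W = matrix(0, k * in_ch, out_ch), b = numeric(out_ch))
}

nn_pool <- function(k, stride = 1) list(type = "pool", k = k, stride = stride)

# Residual block: two same-padded convolutions with a ReLU between, plus an
# identity skip (1x1 projection when the channel count changes), ReLU after
# the sum. Same-padding keeps the temporal length, which is what makes the
# identity skip well-defined.
nn_resblock <- function(k, in_ch, out_ch) {
  pad <- (k - 1) %/% 2
  proj <- if (in_ch != out_ch) nn_conv(1, in_ch, out_ch, pad = 0) else NULL
  list(type = "resblock",
       conv1 = nn_conv(k, in_ch, out_ch, pad = pad),
       conv2 = nn_conv(k, out_ch, out_ch, pad = pad),
       proj = proj)
}

conv_out_len <- function(L, layer) {
  switch(layer$type,
         conv = L + 2 * layer$pad - layer$k + 1,
         pool = (L - layer$k) %/% layer$stride + 1,
         resblock = L,
         L)
}

# ---- parameter bookkeeping -------------------------------------------------

nn_init_layer <- function(layer) {
  he <- function(W, fan_in) matrix(stats::rnorm(length(W), 0, sqrt(2 / fan_in)),
                                   nrow(W), ncol(W))
  if (layer$type == "dense") {
    layer$W <- he(layer$W, layer$n_in); layer$b[] <- 0
  } else if (layer$type == "conv") {
    layer$W <- he(layer$W, layer$k * layer$in_ch); layer$b[] <- 0
  } else if (layer$type == "resblock") {
    layer$conv1 <- nn_init_layer(layer$conv1)
    layer$conv2 <- nn_init_layer(layer$conv2)
    if (!is.null(layer$proj)) layer$proj <- nn_init_layer(layer$proj)
  }
  layer
}

# Deep copies of all trainable parameters (for checkpointing).
nn_get_params <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("dense", "conv")) list(W = l$W, b = l$b)
    else if (l$type == "resblock") {
      list(conv1 = list(W = l$conv1$W, b = l$conv1$b),
           conv2 = list(W = l$conv2$W, b = l$conv2$b),
           proj = if (!is.null(l$proj)) list(W = l$proj$W, b = l$proj$b))
    } else NULL
  })
}

nn_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- params[[i]]
    if (is.null(p)) next
    if (l$type %in% c("dense", "conv")) { l$W <- p$W; l$b <- p$b }
    else if (l$type == "resblock") {
      l$conv1$W <- p$conv1$W; l$conv1$b <- p$conv1$b
      l$conv2$W <- p$conv2$W; l$conv2$b <- p$conv2$b
      if (!is.null(l$proj)) { l$proj$W <- p$proj$W; l$proj$b <- p$proj$b }
    }
    layers[[i]] <- l
  }
  layers
}

# ---- single-layer forward / backward --------------------------------------

conv_forward <- function(layer, X) {
  d <- dim(X)
  f <- conv1d_fwd_cache(X, layer$W, layer$b, d[1], d[2], d[3], layer$pad)
  list(out = f$out, cache = list(Xcol = f$Xcol, dimX = d))
}

conv_backward <- function(layer, cache, dY, need_dx = TRUE) {
  d <- cache$dimX
  r <- conv1d_bwd_cached(cache$Xcol, layer$W, dY, d[1], d[2], d[3],
                         layer$pad, need_dx)
  list(dX = r$dX, grads = list(W = r$W, b = r$b))
}

pool_forward <- function(layer, X) {
  d <- dim(X)
  r <- pool1d_fwd(X, d[1], d[2], d[3], layer$k, layer$stride)
  list(out = r$out, cache = list(arg = r$arg, dimX = d))
}

pool_backward <- function(layer, cache, dY) {
  d <- cache$dimX
  list(dX = pool1d_bwd(dY, cache$arg, d[1], d[2], d[3], layer$k,
                       layer$stride),
       grads = NULL)
}

dense_forward <- function(layer, X) {
  Y <- X %*% layer$W
  Y <- sweep(Y, 2, layer$b, `+`)
  list(out = Y, cache = list(X = X))
}

dense_backward <- function(layer, cache, dY) {
  list(dX = tcrossprod(dY, layer$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

relu_forward <- function(X) {
  out <- relu_fwd_cpp(X)
  list(out = out, cache = list(out = out))
}
relu_backward <- function(cache, dY) {
  list(dX = relu_bwd_cpp(dY, cache$out), grads = NULL)
}

resblock_forward <- function(layer, X) {
  f1 <- conv_forward(layer$conv1, X)
  r1 <- relu_forward(f1$out)
  f2 <- conv_forward(layer$conv2, r1$out)
  skip <- if (is.null(layer$proj)) list(out = X, cache = NULL) else
    conv_forward(layer$proj, X)
  pre <- f2$out + skip$out
  r2 <- relu_forward(pre)
  list(out = r2$out,
       cache = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                    skip = skip$cache, r2 = r2$cache))
}

resblock_backward <- function(layer, cache, dY, need_dx = TRUE) {
  dpre <- relu_backward(cache$r2, dY)$dX
  b2 <- conv_backward(layer$conv2, cache$f2, dpre)
  dr1 <- relu_backward(cache$r1, b2$dX)$dX
  b1 <- conv_backward(layer$conv1, cache$f1, dr1, need_dx = need_dx)
  if (is.null(layer$proj)) {
    dX <- if (need_dx) b1$dX + dpre else NULL
    gproj <- NULL
  } else {
    bp <- conv_backward(layer$proj, cache$skip, dpre, need_dx = need_dx)
    dX <- if (need_dx) b1$dX + bp$dX else NULL
    gproj <- bp$grads
  }
  list(dX = dX, grads = list(conv1 = b1$grads, conv2 = b2$grads, proj = gproj))
}

layer_forward <- function(layer, X) {
  switch(layer$type,
         dense = dense_forward(layer, X),
         conv = conv_forward(layer, X),
         pool = pool_forward(layer, X),
         relu = relu_forward(X),
         resblock = resblock_forward(layer, X),
         stop_cfg("unknown layer type '%s'", layer$type))
}

layer_backward <- function(layer, cache, dY, need_dx = TRUE) {
  switch(layer$type,
         dense = dense_backward(layer, cache, dY),
         conv = conv_backward(layer, cache, dY, need_dx = need_dx),
         pool = pool_backward(layer, cache, dY),
         relu = relu_backward(cache, dY),
         resblock = resblock_backward(layer, cache, dY, need_dx = need_dx),
         stop_cfg("unknown layer type '%s'", layer$type))
}

seq_forward <- function(layers, X) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], X)
    X <- f$out
    caches[[i]] <- f$cache
  }
  list(out = X, caches = caches)
}

seq_backward <- function(layers, caches, dY, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_backward(layers[[i]], caches[[i]], dY,
                        need_dx = need_input_grad || i > 1)
    dY <- b$dX
    grads[i] <- list(b$grads)  # keep NULL placeholders for layers without params
  }
  list(dX = dY, grads = grads)
}

# [L, B, C] -> [B, L*C] (channel-major per sample) and its inverse.
flatten_tensor <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3])
}

unflatten_tensor <- function(M, L, C) {
  B <- nrow(M)
  aperm(array(M, c(B, L, C)), c(2, 1, 3))
}

# ---- full-network forward / backward --------------------------------------

# net: list(tensor_layers, matrix_layers, head_layers, hybrid, input_kind,
#           flat_len, flat_ch)
net_forward <- function(net, Xw = NULL, Xf = NULL, need_cache = FALSE) {
  cache <- list()
  M <- NULL
  if (length(net$tensor_layers)) {
    if (is.null(Xw)) stop_cfg("model expects window input")
    tf <- seq_forward(net$tensor_layers, Xw)
    cache$tensor <- tf$caches
    M <- flatten_tensor(tf$out)
    if (length(net$matrix_layers)) {
      mf <- seq_forward(net$matrix_layers, M)
      cache$matrix <- mf$caches
      M <- mf$out
    }
  }
  if (net$hybrid) {
    if (is.null(Xf)) stop_cfg("hybrid model expects feature input")
    cache$backbone_width <- ncol(M)
    M <- cbind(M, Xf)
  } else if (is.null(M)) {
    if (is.null(Xf)) stop_cfg("model expects feature input")
    M <- Xf
  }
  nh <- length(net$head_layers)
  if (nh > 1) {
    hf <- seq_forward(net$head_layers[-nh], M)
    cache$head <- hf$caches
    emb <- hf$out
  } else {
    cache$head <- list()
    emb <- M
  }
  ff <- layer_forward(net$head_layers[[nh]], emb)
  cache$final <- ff$cache
  list(logits = ff$out, embedding = emb, cache = if (need_cache) cache)
}

net_backward <- function(net, cache, dlogits) {
  nh <- length(net$head_layers)
  fb <- layer_backward(net$head_layers[[nh]], cache$final, dlogits)
  grads_head <- vector("list", nh)
  grads_head[[nh]] <- fb$grads
  dM <- fb$dX
  if (nh > 1) {
    hb <- seq_backward(net$head_layers[-nh], cache$head, dM)
    grads_head[seq_len(nh - 1)] <- hb$grads
    dM <- hb$dX
  }
  if (net$hybrid) dM <- dM[, seq_len(cache$backbone_width), drop = FALSE]
  grads_matrix <- NULL
  grads_tensor <- NULL
  if (length(net$tensor_layers)) {
    if (length(net$matrix_layers)) {
      mb <- seq_backward(net$matrix_layers, cache$matrix, dM)
      grads_matrix <- mb$grads
      dM <- mb$dX
    }
    dT <- unflatten_tensor(dM, net$flat_len, net$flat_ch)
    tb <- seq_backward(net$tensor_layers, cache$tensor, dT,
                       need_input_grad = FALSE)
    grads_tensor <- tb$grads
  }
  list(tensor = grads_tensor, matrix = grads_matrix, head = grads_head)
}

net_init <- function(net, seed = NULL) {
  with_seed(seed, {
    net$tensor_layers <- lapply(net$tensor_layers, nn_init_layer)
    net$matrix_layers <- lapply(net$matrix_layers, nn_init_layer)
    net$head_layers <- lapply(net$head_layers, nn_init_layer)
    net
  })
}

net_get_params <- function(net) {
  list(tensor = nn_get_params(net$tensor_layers),
       matrix = nn_get_params(net$matrix_layers),
       head = nn_get_params(net$head_layers))
}

net_set_params <- function(net, params) {
  net$tensor_layers <- nn_set_params(net$tensor_layers, params$tensor)
  net$matrix_layers <- nn_set_params(net$matrix_layers, params$matrix)
  net$head_layers <- nn_set_params(net$head_layers, params$head)
  net
}

# ---- Adam ------------------------------------------------------------------

# Walks the nested parameter/gradient structures in lock-step.
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_leaf <- function(p, g, s) {
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    r <- adam_leaf_cpp(p, g, s$m, s$v, lr, beta1, beta2, eps, t)
    list(p = r$p, s = list(m = r$m, v = r$v))
  }
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.numeric(p)) return(step_leaf(p, g, s))
    if (is.null(s)) s <- vector("list", length(p))
    for (nm in names(p)) {
      if (is.null(p[[nm]]) || is.null(g[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], s[[nm]])
      p[[nm]] <- r$p
      s[[nm]] <- r$s
    }
    if (is.null(names(p))) {
      for (i in seq_along(p)) {
        if (is.null(p[[i]]) || is.null(g[[i]])) next
        r <- walk(p[[i]], g[[i]], s[[i]])
        p[[i]] <- r$p
        s[[i]] <- r$s
      }
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

# ---- loss ------------------------------------------------------------------

# Class-weighted softmax cross-entropy; weights follow the convention of
# normalizing by the summed weights of the batch. Returns loss and dlogits.
weighted_ce <- function(logits, y, weights) {
  B <- nrow(logits)
  mx <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) mx <- pmax(mx, logits[, j])
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  wy <- weights[y]
  wsum <- sum(wy)
  if (wsum <= 0) stop_cfg("all batch samples have zero class weight")
  nll <- -log(pmax(p[cbind(seq_len(B), y)], 1e-12))
  onehot <- matrix(0, B, ncol(logits))
  onehot[cbind(seq_len(B), y)] <- 1
  list(loss = sum(wy * nll) / wsum,
       dlogits = (p - onehot) * wy / wsum)
}

# Early stopping scan over a completed validation-loss history: the
# checkpoint is the first global minimum, training stops the first time
# `patience` epochs pass without a new minimum (or at the epoch cap).
early_stop_epoch <- function(val_losses, patience = 30, max_epochs = 140) {
  best <- Inf; best_epoch <- 0; stop_epoch <- min(length(val_losses), max_epochs)
  for (e in seq_len(min(length(val_losses), max_epochs))) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e
    } else if (e - best_epoch >= patience) {
      stop_epoch <- e
      break
    }
  }
  list(stop_epoch = stop_epoch, checkpoint_epoch = best_epoch)
}
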