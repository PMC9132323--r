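# Minimal convolutional-network primitives on dense arrays.
#
# Activations are [H, W, C, N] arrays. The im2col/col2im gathers, layout
# permutations and 2x2 max-pooling run in compiled code (src/conv_ops.cpp);
# the convolution itself is a BLAS matrix product over the patch matrix.
# Everything here is deterministic given the RNG state.

conv_dims <- function(H, k, stride, pad) {
  out <- (H + 2 * pad - k) / stride + 1
  if (out != floor(out)) stop("conv geometry does not tile the input")
  as.integer(out)
}

conv_plan <- function(H, W, C, k, stride, pad) {
  list(OH = conv_dims(H, k, stride, pad), OW = conv_dims(W, k, stride, pad))
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  pl <- layer$plan
  xcol <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                     layer$pad, pl$OH, pl$OW)
  wmat <- matrix(layer$W, nrow(xcol), layer$n_out)
  out <- crossprod(wmat, xcol) + layer$b
  y <- gemm_to_spatial_cpp(out, pl$OH, pl$OW, layer$n_out, d[4])
  list(y = y, xcol = xcol, in_dim = d)
}

conv_backward <- function(dy, layer, cache) {
  pl <- layer$plan
  d <- cache$in_dim
  dout <- spatial_to_gemm_cpp(dy, pl$OH, pl$OW, layer$n_out, d[4])
  dW <- array(tcrossprod(cache$xcol, dout), dim = dim(layer$W))
  db <- rowSums(dout)
  wmat <- matrix(layer$W, nrow(cache$xcol), layer$n_out)
  dxcol <- wmat %*% dout
  dx <- col2im_cpp(dxcol, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                   layer$pad, pl$OH, pl$OW)
  list(dx = dx, dW = dW, db = db)
}

# Forward pass through the whole network; returns logits and layer caches.
net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      cf <- conv_forward(x, l); caches[[i]] <- cf; x <- cf$y
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = x > 0); x <- x * caches[[i]]$mask
    } else if (l$type == "maxpool") {
      d <- dim(x)
      mp <- maxpool2_fwd_cpp(x, d[1], d[2], d[3], d[4])
      caches[[i]] <- list(arg = mp$arg, in_dim = d)
      x <- mp$y
    } else if (l$type == "flatten") {
      d <- dim(x); caches[[i]] <- list(in_dim = d)
      x <- matrix(x, prod(d[-length(d)]), d[length(d)])
    } else if (l$type == "linear") {
      caches[[i]] <- list(x = x)
      x <- crossprod(l$W, x) + l$b
    } else stop("unknown layer type: ", l$type)
  }
  list(logits = x, caches = caches)
}

# Backward pass; returns per-layer parameter gradients.
net_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      g <- conv_backward(dy, l, caches[[i]])
      grads[[i]] <- list(W = g$dW, b = g$db); dy <- g$dx
    } else if (l$type == "relu") {
      dy <- dy * caches[[i]]$mask
    } else if (l$type == "maxpool") {
      d <- caches[[i]]$in_dim
      dy <- maxpool2_bwd_cpp(dy, caches[[i]]$arg, d[1], d[2], d[3], d[4])
    } else if (l$type == "flatten") {
      dy <- array(dy, caches[[i]]$in_dim)
    } else if (l$type == "linear") {
      grads[[i]] <- list(W = tcrossprod(caches[[i]]$x, dy), b = rowSums(dy))
      dy <- l$W %*% dy
    }
  }
  grads
}

# Softmax cross-entropy over logits (n_classes x N).
softmax_ce <- function(logits, labels) {
  N <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(z); p <- sweep(p, 2, colSums(p), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(N))] <- dlogits[cbind(labels, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

# One Adam step on a layer's parameters.
adam_step <- function(layer, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (p in c("W", "b")) {
    g <- grad[[p]]
    state$m[[p]] <- beta1 * state$m[[p]] + (1 - beta1) * g
    state$v[[p]] <- beta2 * state$v[[p]] + (1 - beta2) * g^2
    mhat <- state$m[[p]] / (1 - beta1^t)
    vhat <- state$v[[p]] / (1 - beta2^t)
    layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(layer = layer, state = state)
}
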