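## Layer primitives for the RFC-Net engine.
##
## A feature tensor is a numeric matrix with one row per channel and
## H*W*N columns (spatial index column-major, samples concatenated), carrying
## attributes h, w, n. Each layer is a plain list with a $type, its trainable
## parameter matrices, and (for batch norm) running statistics. Forward passes
## return list(out, cache); backward passes consume the cache and return
## list(dx, grads) with grads named like the layer's parameters.

## Tensor dims (h, w, n) ride along as a single attribute, set in place in
## C++ (every ft() call site owns its freshly created matrix).
ft <- function(m, h, w, n) .cpp_set_td(m, c(h, w, n))
ft_dims <- function(x) attr(x, "td")

he_init <- function(rows, cols, fan_in) {
  matrix(stats::rnorm(rows * cols, sd = sqrt(2 / fan_in)), rows, cols)
}

## Pack a 3 x 3 x cin x cout kernel array into the engine's matrix layout:
## rows = output channels, column index = tap*cin + cin_index with tap
## k = (dc+1)*3 + (dr+1) for offsets dr, dc in {-1, 0, 1}.
kernel_pack <- function(K) {
  kd <- dim(K)
  W <- matrix(0, kd[4], 9 * kd[3])
  for (dc in 0:2) for (dr in 0:2) {
    k <- dc * 3 + dr
    W[, k * kd[3] + seq_len(kd[3])] <- t(matrix(K[dr + 1, dc + 1, , ], kd[3]))
  }
  W
}

new_bn <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rmean = rep(0, channels), rvar = rep(1, channels))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## Fused BN (+ optional ReLU) forward/backward, dispatching to the C++
## kernels. In training mode batch statistics are used and running ones
## updated; in eval mode the stored running statistics apply.
fused_fwd <- function(z, bn, training, relu) {
  if (training) {
    r <- .cpp_bn_relu_train(z, bn$gamma, bn$beta, BN_EPS, relu)
    v <- as.vector(r$sd)^2 - BN_EPS
    list(out = r$out,
         cache = list(xhat = r$xhat, sd = as.vector(r$sd), out = r$out,
                      gamma = bn$gamma, relu = relu),
         rstats = list(
           rmean = (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * as.vector(r$mu),
           rvar = (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * v))
  } else {
    list(out = .cpp_bn_relu_eval(z, bn$gamma, bn$beta, bn$rmean, bn$rvar,
                                 BN_EPS, relu),
         cache = NULL, rstats = NULL)
  }
}

fused_bwd <- function(dy, cache) {
  .cpp_bn_relu_bwd(dy, cache$out, cache$xhat, cache$gamma, cache$sd,
                   cache$relu)
}

## ---- conv + BN + ReLU -------------------------------------------------------

new_cbr <- function(cin, cout, stride = 1L, relu = TRUE) {
  list(type = "cbr", cin = cin, cout = cout, stride = as.integer(stride),
       relu = relu, W = NULL, bn = new_bn(cout))
}

cbr_init <- function(layer) {
  layer$W <- he_init(layer$cout, layer$cin * 9, layer$cin * 9)
  layer
}

cbr_fwd <- function(layer, x, training) {
  d <- ft_dims(x)
  z <- .cpp_conv_fwd(x, layer$W, d[1], d[2], d[3], layer$stride)
  f <- fused_fwd(z, layer$bn, training, layer$relu)
  ho <- if (layer$stride == 2L) d[1] %/% 2L else d[1]
  wo <- if (layer$stride == 2L) d[2] %/% 2L else d[2]
  list(out = ft(f$out, ho, wo, d[3]),
       cache = list(x = x, dims = d, bn = f$cache),
       rstats = f$rstats)
}

cbr_bwd <- function(layer, dy, cache) {
  b <- fused_bwd(dy, cache$bn)
  d <- cache$dims
  cv <- .cpp_conv_bwd(cache$x, b$dx, layer$W, d[1], d[2], d[3], layer$stride)
  list(dx = ft(cv$dx, d[1], d[2], d[3]),
       grads = list(W = cv$dw, gamma = as.vector(b$dgamma),
                    beta = as.vector(b$dbeta)))
}

## ---- transposed conv + BN + ReLU (stride-2 upsampling) ----------------------

new_deconv <- function(cin, cout) {
  list(type = "deconv", cin = cin, cout = cout, W = NULL, bn = new_bn(cout))
}

deconv_init <- function(layer) {
  layer$W <- he_init(layer$cin, layer$cout * 9, layer$cin * 9)
  layer
}

deconv_fwd <- function(layer, x, training) {
  d <- ft_dims(x)
  z <- .cpp_deconv_fwd(x, layer$W, d[1], d[2], d[3])
  f <- fused_fwd(z, layer$bn, training, TRUE)
  list(out = ft(f$out, 2L * d[1], 2L * d[2], d[3]),
       cache = list(x = x, dims = d, bn = f$cache),
       rstats = f$rstats)
}

deconv_bwd <- function(layer, dy, cache) {
  b <- fused_bwd(dy, cache$bn)
  d <- cache$dims
  cv <- .cpp_deconv_bwd(cache$x, b$dx, layer$W, d[1], d[2], d[3])
  list(dx = ft(cv$dx, d[1], d[2], d[3]),
       grads = list(W = cv$dw, gamma = as.vector(b$dgamma),
                    beta = as.vector(b$dbeta)))
}

## ---- recurrent convolutional layer ------------------------------------------
##
## y(0)   = ReLU(BN_0(conv(x; Wx)))
## y(t)   = ReLU(BN_t(conv(x; Wx) + conv(y(t-1); Wr))),  t = 1..t_steps
## The feedforward response conv(x; Wx) is computed once and reused at every
## step; Wr is shared across steps. When cin == cout the recurrent kernel IS
## the feedforward kernel (full weight sharing); otherwise Wr is a dedicated
## 3x3 kernel. Convolutions are bias-free; each unfolding step has its own
## BN affine pair.

new_rcl <- function(cin, cout, t_steps = 2L) {
  list(type = "rcl", cin = cin, cout = cout, t_steps = as.integer(t_steps),
       shared = cin == cout, W = NULL, Wr = NULL,
       bns = lapply(seq_len(t_steps + 1L), function(i) new_bn(cout)))
}

rcl_init <- function(layer) {
  layer$W <- he_init(layer$cout, layer$cin * 9, layer$cin * 9)
  if (!layer$shared)
    layer$Wr <- he_init(layer$cout, layer$cout * 9, layer$cout * 9)
  layer
}

rcl_kernel_r <- function(layer) if (layer$shared) layer$W else layer$Wr

rcl_fwd <- function(layer, x, training) {
  d <- ft_dims(x)
  f <- .cpp_conv_fwd(x, layer$W, d[1], d[2], d[3], 1L)
  Wr <- rcl_kernel_r(layer)
  steps <- vector("list", layer$t_steps + 1L)
  rstats <- vector("list", layer$t_steps + 1L)
  y <- NULL
  for (t in 0:layer$t_steps) {
    z <- if (t == 0L) f else f + .cpp_conv_fwd(y, Wr, d[1], d[2], d[3], 1L)
    b <- fused_fwd(z, layer$bns[[t + 1L]], training, TRUE)
    steps[[t + 1L]] <- list(y_prev = y, bn = b$cache)
    rstats[t + 1L] <- list(b$rstats)
    y <- b$out
  }
  list(out = ft(y, d[1], d[2], d[3]),
       cache = list(x = x, dims = d, steps = steps),
       rstats = rstats)
}

rcl_bwd <- function(layer, dy, cache) {
  d <- cache$dims
  Wr <- rcl_kernel_r(layer)
  df <- 0
  dWr <- NULL
  dbns <- vector("list", layer$t_steps + 1L)
  for (t in layer$t_steps:0) {
    st <- cache$steps[[t + 1L]]
    dz <- fused_bwd(dy, st$bn)
    dbns[[t + 1L]] <- list(gamma = as.vector(dz$dgamma),
                           beta = as.vector(dz$dbeta))
    df <- df + dz$dx
    if (t > 0L) {
      cv <- .cpp_conv_bwd(st$y_prev, dz$dx, Wr, d[1], d[2], d[3], 1L)
      dWr <- if (is.null(dWr)) cv$dw else dWr + cv$dw
      dy <- cv$dx
    }
  }
  cv <- .cpp_conv_bwd(cache$x, df, layer$W, d[1], d[2], d[3], 1L)
  dW <- cv$dw
  grads <- list()
  if (layer$shared) {
    grads$W <- dW + if (is.null(dWr)) 0 else dWr
  } else {
    grads$W <- dW
    grads$Wr <- if (is.null(dWr)) matrix(0, layer$cout, layer$cout * 9) else dWr
  }
  grads$bns <- dbns
  list(dx = ft(cv$dx, d[1], d[2], d[3]), grads = grads)
}

## ---- output head: 3x3 conv with bias, no BN, no activation ------------------

new_head <- function(cin, n_classes = 3L) {
  list(type = "head", cin = cin, cout = as.integer(n_classes),
       W = NULL, b = rep(0, n_classes))
}

head_init <- function(layer) {
  layer$W <- he_init(layer$cout, layer$cin * 9, layer$cin * 9)
  layer
}

head_fwd <- function(layer, x) {
  d <- ft_dims(x)
  z <- .cpp_conv_fwd(x, layer$W, d[1], d[2], d[3], 1L) + layer$b
  list(out = ft(z, d[1], d[2], d[3]), cache = list(x = x, dims = d))
}

head_bwd <- function(layer, dy, cache) {
  d <- cache$dims
  cv <- .cpp_conv_bwd(cache$x, dy, layer$W, d[1], d[2], d[3], 1L)
  list(dx = ft(cv$dx, d[1], d[2], d[3]),
       grads = list(W = cv$dw, b = rowSums(dy)))
}

## Generic dispatch ------------------------------------------------------------

layer_init <- function(layer) {
  switch(layer$type,
         cbr = cbr_init(layer),
         deconv = deconv_init(layer),
         rcl = rcl_init(layer),
         head = head_init(layer))
}

layer_fwd <- function(layer, x, training) {
  switch(layer$type,
         cbr = cbr_fwd(layer, x, training),
         deconv = deconv_fwd(layer, x, training),
         rcl = rcl_fwd(layer, x, training),
         head = head_fwd(layer, x))
}

layer_bwd <- function(layer, dy, cache) {
  switch(layer$type,
         cbr = cbr_bwd(layer, dy, cache),
         deconv = deconv_bwd(layer, dy, cache),
         rcl = rcl_bwd(layer, dy, cache),
         head = head_bwd(layer, dy, cache))
}

## Number of trainable scalars in a layer (kernels, biases, BN affine pairs).
layer_n_params <- function(layer, kernels_only = FALSE) {
  n <- length(layer[["W"]])
  n <- n + length(layer[["Wr"]])
  if (kernels_only) return(n)
  n <- n + length(layer[["b"]])
  bn <- layer[["bn"]]
  if (!is.null(bn)) n <- n + length(bn$gamma) + length(bn$beta)
  bns <- layer[["bns"]]
  if (!is.null(bns))
    n <- n + sum(vapply(bns, function(b) length(b$gamma) + length(b$beta), 0))
  n
}
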