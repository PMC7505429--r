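#' Network architecture specification
#'
#' Describes an RFC-Net: a 4-level encoder-decoder with a multi-scale input
#' pyramid, strided-convolution downsampling, transposed-convolution
#' upsampling, skip connections, and five deeply supervised 3-class outputs
#' (one head per decoder scale plus the final full-resolution map).
#'
#' The default (full-scale) configuration takes 512 x 512 RGB input, encoder
#' widths 32/64/128/256 and a 512-channel bottleneck. Each encoder/decoder
#' level holds one variant block (see [build_unit()]) followed by
#' `n_extra_convs` plain 3 x 3 conv+BN+ReLU layers. The pyramid image at each
#' scale is passed through a 3 x 3 convolution (widths
#' `pyramid_conv_widths`) and concatenated with the incoming encoder
#' features. These free widths are calibrated so that the assembled network
#' has exactly 11,016,684 trainable parameters with `variant = "basic"` and
#' 18,883,436 with `variant = "stack_recurrent"`
#' (see `scripts/calibrate_architecture.R` in the source repository).
#'
#' @param input_size input side length in pixels; must be divisible by 16.
#' @param encoder_widths channel widths of the four encoder levels.
#' @param bottleneck bottleneck width.
#' @param pyramid_conv_widths widths of the three pyramid-injection convs.
#' @param n_extra_convs plain convs per level after the variant block.
#' @param variant one of `"basic"`, `"recurrent"`, `"stack_recurrent"`,
#'   `"recurrent_basic"`, `"stack_recurrent_basic"`.
#' @param t_steps recurrent unfolding steps (evaluated at t = 0..t_steps).
#' @param n_classes number of output classes (3: background / disc / cup).
#' @param loss_weights per-output loss weights, length 5, coarsest head
#'   first, final full-resolution output last.
#' @param skip_fusion `"concat"` (default) or `"add"`.
#' @return an object of class `rfc_spec`.
#' @export
network_spec <- function(input_size = 512L,
                         encoder_widths = c(32L, 64L, 128L, 256L),
                         bottleneck = 512L,
                         pyramid_conv_widths = c(96L, 129L, 256L),
                         n_extra_convs = 3L,
                         variant = c("basic", "recurrent", "stack_recurrent",
                                     "recurrent_basic", "stack_recurrent_basic"),
                         t_steps = 2L,
                         n_classes = 3L,
                         loss_weights = c(0.1, 0.1, 0.1, 0.1, 0.6),
                         skip_fusion = c("concat", "add")) {
  variant <- match.arg(variant)
  skip_fusion <- match.arg(skip_fusion)
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16")
  if (length(encoder_widths) != 4L)
    stop("encoder_widths must have length 4")
  if (length(pyramid_conv_widths) != 3L)
    stop("pyramid_conv_widths must have length 3")
  if (length(loss_weights) != 5L)
    stop("loss_weights must have length 5")
  if (t_steps < 0L) stop("t_steps must be >= 0")
  spec <- list(input_size = as.integer(input_size),
               encoder_widths = as.integer(encoder_widths),
               bottleneck = as.integer(bottleneck),
               pyramid_conv_widths = as.integer(pyramid_conv_widths),
               n_extra_convs = as.integer(n_extra_convs),
               variant = variant, t_steps = as.integer(t_steps),
               n_classes = as.integer(n_classes),
               pyramid_sizes = as.integer(input_size / c(1L, 2L, 4L, 8L)),
               n_outputs = 5L,
               loss_weights = loss_weights,
               skip_fusion = skip_fusion)
  class(spec) <- "rfc_spec"
  spec
}

#' Desk-scale network specification
#'
#' A reduced configuration (64 x 64 input, widths 8/16/32/64) with the same
#' topology as the full-scale network, sized so that training runs in
#' minutes on a single CPU core.
#'
#' @param ... overrides passed to [network_spec()].
#' @export
desk_spec <- function(...) {
  args <- list(input_size = 64L, encoder_widths = c(8L, 16L, 32L, 64L),
               bottleneck = 128L, pyramid_conv_widths = c(16L, 32L, 64L))
  args[names(list(...))] <- list(...)
  do.call(network_spec, args)
}

#' Build one block of a given unit variant
#'
#' The five block variants: `basic` is a single 3 x 3 conv + BN + ReLU;
#' `recurrent` is a recurrent convolutional layer (RCL) whose feedforward
#' response is recomputed into every unfolding step; `stack_recurrent` is two
#' recurrent units in sequence; `recurrent_basic` is a basic unit followed by
#' an RCL; `stack_recurrent_basic` is two of those. Convolution kernels are
#' shared across unfolding steps, and a recurrent unit whose input and output
#' widths are equal reuses its feedforward kernel as the recurrent kernel, so
#' recurrence adds no convolution parameters there.
#'
#' @param variant variant name (see [network_spec()]).
#' @param channels_in,channels_out widths.
#' @param t_steps recurrent unfolding steps.
#' @param init initialise weights (TRUE) or leave placeholders.
#' @return list of layer objects (the block), with attribute `"widths"`.
#' @export
build_unit <- function(variant, channels_in, channels_out, t_steps = 2L,
                       init = TRUE) {
  layers <- switch(variant,
    basic = list(new_cbr(channels_in, channels_out)),
    recurrent = list(new_rcl(channels_in, channels_out, t_steps)),
    stack_recurrent = list(new_rcl(channels_in, channels_out, t_steps),
                           new_rcl(channels_out, channels_out, t_steps)),
    recurrent_basic = list(new_cbr(channels_in, channels_out),
                           new_rcl(channels_out, channels_out, t_steps)),
    stack_recurrent_basic = list(new_cbr(channels_in, channels_out),
                                 new_rcl(channels_out, channels_out, t_steps),
                                 new_cbr(channels_out, channels_out),
                                 new_rcl(channels_out, channels_out, t_steps)),
    stop("unknown variant: ", variant)
  )
  if (init) layers <- lapply(layers, layer_init)
  layers
}

#' Count trainable parameters of a block
#'
#' @param block a block from [build_unit()].
#' @param kernels_only count convolution kernel weights only (excludes BN
#'   affine pairs and biases).
#' @export
unit_parameter_count <- function(block, kernels_only = FALSE) {
  sum(vapply(block, layer_n_params, 0, kernels_only = kernels_only))
}

## Ordered layer layout of the network. Each element: name, constructor args.
rfc_layout <- function(spec) {
  w <- spec$encoder_widths
  p <- spec$pyramid_conv_widths
  ne <- spec$n_extra_convs
  concat <- spec$skip_fusion == "concat"
  L <- list()
  add <- function(L, name, what) { L[[name]] <- what; L }
  blockdef <- function(cin, cout) list(kind = "block", cin = cin, cout = cout)
  convdef <- function(cin, cout, stride = 1L)
    list(kind = "conv", cin = cin, cout = cout, stride = stride)
  deconvdef <- function(cin, cout) list(kind = "deconv", cin = cin, cout = cout)
  headdef <- function(cin) list(kind = "head", cin = cin)

  L <- add(L, "enc1_block", blockdef(3L, w[1]))
  for (i in seq_len(ne)) L <- add(L, paste0("enc1_conv", i), convdef(w[1], w[1]))
  pin <- c(NA, p)  # pyramid conv width per level 2..4
  for (l in 2:4) {
    L <- add(L, paste0("down", l - 1), convdef(w[l - 1], w[l - 1], 2L))
    L <- add(L, paste0("pyr", l), convdef(3L, pin[l]))
    L <- add(L, paste0("enc", l, "_block"), blockdef(w[l - 1] + pin[l], w[l]))
    for (i in seq_len(ne))
      L <- add(L, paste0("enc", l, "_conv", i), convdef(w[l], w[l]))
  }
  L <- add(L, "down4", convdef(w[4], w[4], 2L))
  L <- add(L, "bott_block", blockdef(w[4], spec$bottleneck))
  up_in <- c(spec$bottleneck, w[4], w[3], w[2])
  for (j in 1:4) {
    l <- 5 - j  # decoder level 4,3,2,1
    L <- add(L, paste0("up", l), deconvdef(up_in[j], w[l]))
    L <- add(L, paste0("dec", l, "_block"),
             blockdef(if (concat) 2L * w[l] else w[l], w[l]))
    for (i in seq_len(ne))
      L <- add(L, paste0("dec", l, "_conv", i), convdef(w[l], w[l]))
    L <- add(L, paste0("head", l), headdef(w[l]))
  }
  L <- add(L, "final_head", headdef(w[1]))
  L
}

#' Assemble the full RFC-Net
#'
#' Builds the encoder-decoder of [network_spec()]: four encoder levels with
#' pyramid injection, stride-2 convolution downsampling, a bottleneck block,
#' four decoder levels with 3 x 3 transposed-convolution upsampling and skip
#' connections, and five supervised 3-class output heads. Every convolution
#' is followed by batch normalisation and ReLU except the output heads.
#'
#' @param spec an `rfc_spec`.
#' @param seed integer seed for He-normal weight initialisation.
#' @return an object of class `rfc_model` (mutable: layers live in an
#'   environment).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rfc_spec"))
  layout <- rfc_layout(spec)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (nm in names(layout)) {
    d <- layout[[nm]]
    obj <- switch(d$kind,
      block = build_unit(spec$variant, d$cin, d$cout, spec$t_steps),
      conv = list(layer_init(new_cbr(d$cin, d$cout, d$stride))),
      deconv = list(layer_init(new_deconv(d$cin, d$cout))),
      head = list(layer_init(new_head(d$cin, spec$n_classes))))
    assign(nm, obj, envir = env)
  }
  model <- list(spec = spec, env = env, names = names(layout))
  class(model) <- "rfc_model"
  model
}

#' Count trainable parameters of a model
#'
#' Sums all trainable scalars: convolution kernels, output-head biases, and
#' batch-normalisation affine pairs. Running BN statistics are not counted.
#'
#' @param model an `rfc_model`.
#' @param kernels_only count convolution kernel weights only.
#' @export
count_parameters <- function(model, kernels_only = FALSE) {
  stopifnot(inherits(model, "rfc_model"))
  tot <- 0
  for (nm in model$names)
    tot <- tot + unit_parameter_count(get(nm, envir = model$env), kernels_only)
  tot
}

## 2x average-pool downsampling of an image tensor (used for the pyramid).
avgpool2 <- function(x) {
  d <- ft_dims(x)
  a <- array(x, c(nrow(x), d[1], d[2], d[3]))
  oi <- seq(1, d[1], by = 2)
  oj <- seq(1, d[2], by = 2)
  out <- (a[, oi, oj, , drop = FALSE] + a[, oi + 1, oj, , drop = FALSE] +
          a[, oi, oj + 1, , drop = FALSE] + a[, oi + 1, oj + 1, , drop = FALSE]) / 4
  ft(matrix(out, nrow(x)), d[1] %/% 2L, d[2] %/% 2L, d[3])
}

## Run a chain of layers (a block or plain-conv run). Returns out + caches.
chain_fwd <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  rstats <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x, training)
    x <- r$out
    caches[i] <- list(r$cache)
    rstats[i] <- list(r$rstats)
  }
  list(out = x, caches = caches, rstats = rstats)
}

chain_bwd <- function(layers, dy, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], dy, caches[[i]])
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

## Full network forward pass.
## x: 3 x (S*S*N) tensor in [0,1]. Returns the five output logit maps
## (coarsest first, final full-resolution last) and, when `training`, the
## caches needed for the backward pass.
net_forward <- function(model, x, training = FALSE) {
  env <- model$env
  ne <- model$spec$n_extra_convs
  run <- function(names, x) {
    caches <- list()
    for (nm in names) {
      r <- chain_fwd(get(nm, envir = env), x, training)
      x <- r$out
      caches[[nm]] <- r$caches
      if (training) stash_rstats(env, nm, r$rstats)
    }
    list(out = x, caches = caches)
  }
  lvl <- function(prefix) c(paste0(prefix, "_block"),
                            if (ne > 0) paste0(prefix, "_conv", seq_len(ne)))
  caches <- list()
  pyr <- x
  e <- vector("list", 4)
  r <- run(lvl("enc1"), x); e[[1]] <- r$out; caches <- c(caches, r$caches)
  for (l in 2:4) {
    r <- run(paste0("down", l - 1), e[[l - 1]])
    dn <- r$out; caches <- c(caches, r$caches)
    pyr <- avgpool2(pyr)
    r <- run(paste0("pyr", l), pyr)
    pv <- r$out; caches <- c(caches, r$caches)
    d <- ft_dims(dn)
    xin <- ft(rbind(dn, pv), d[1], d[2], d[3])
    r <- run(lvl(paste0("enc", l)), xin)
    e[[l]] <- r$out; caches <- c(caches, r$caches)
  }
  r <- run("down4", e[[4]]); caches <- c(caches, r$caches)
  r <- run("bott_block", r$out); bt <- r$out; caches <- c(caches, r$caches)

  outputs <- vector("list", 5)
  cur <- bt
  for (j in 1:4) {
    l <- 5 - j
    r <- run(paste0("up", l), cur); up <- r$out; caches <- c(caches, r$caches)
    d <- ft_dims(up)
    s <- if (model$spec$skip_fusion == "concat")
      ft(rbind(up, e[[l]]), d[1], d[2], d[3]) else ft(up + e[[l]], d[1], d[2], d[3])
    r <- run(lvl(paste0("dec", l)), s)
    cur <- r$out; caches <- c(caches, r$caches)
    r <- run(paste0("head", l), cur)
    outputs[[j]] <- r$out; caches <- c(caches, r$caches)
  }
  r <- run("final_head", cur)
  outputs[[5]] <- r$out; caches <- c(caches, r$caches)
  list(outputs = outputs, caches = if (training) caches else NULL)
}

## Write updated BN running statistics back into the model environment.
stash_rstats <- function(env, nm, rstats) {
  layers <- get(nm, envir = env)
  changed <- FALSE
  for (i in seq_along(layers)) {
    rs <- rstats[[i]]
    if (is.null(rs)) next
    if (!is.null(layers[[i]][["bn"]])) {
      layers[[i]]$bn$rmean <- rs$rmean
      layers[[i]]$bn$rvar <- rs$rvar
      changed <- TRUE
    } else if (!is.null(layers[[i]][["bns"]])) {
      for (t in seq_along(rs)) {
        layers[[i]]$bns[[t]]$rmean <- rs[[t]]$rmean
        layers[[i]]$bns[[t]]$rvar <- rs[[t]]$rvar
      }
      changed <- TRUE
    }
  }
  if (changed) assign(nm, layers, envir = env)
}

## Full backward pass. d_outputs: gradients w.r.t. the five logit maps.
## Returns named list of per-layer-chain gradient lists.
net_backward <- function(model, caches, d_outputs) {
  env <- model$env
  ne <- model$spec$n_extra_convs
  grads <- list()
  back <- function(nm, dy) {
    r <- chain_bwd(get(nm, envir = env), dy, caches[[nm]])
    grads[[nm]] <<- r$grads
    r$dx
  }
  lvl <- function(prefix) c(paste0(prefix, "_block"),
                            if (ne > 0) paste0(prefix, "_conv", seq_len(ne)))
  back_lvl <- function(prefix, dy) {
    for (nm in rev(lvl(prefix))) dy <- back(nm, dy)
    dy
  }
  w <- model$spec$encoder_widths
  concat <- model$spec$skip_fusion == "concat"

  d_skip <- vector("list", 4)  # gradient flowing into encoder outputs e[[l]]
  dcur <- back("final_head", d_outputs[[5]])
  for (j in 4:1) {
    l <- 5 - j
    dcur <- dcur + back(paste0("head", l), d_outputs[[j]])
    ds <- back_lvl(paste0("dec", l), dcur)
    d <- ft_dims(ds)
    if (concat) {
      dup <- ft(ds[seq_len(w[l]), , drop = FALSE], d[1], d[2], d[3])
      d_skip[[l]] <- ft(ds[w[l] + seq_len(w[l]), , drop = FALSE], d[1], d[2], d[3])
    } else {
      dup <- ds
      d_skip[[l]] <- ds
    }
    dcur <- back(paste0("up", l), dup)
  }
  dbt <- dcur
  de4 <- back("down4", back("bott_block", dbt)) + d_skip[[4]]
  de <- de4
  for (l in 4:2) {
    dxin <- back_lvl(paste0("enc", l), de)
    d <- ft_dims(dxin)
    cin_dn <- w[l - 1]
    ddn <- ft(dxin[seq_len(cin_dn), , drop = FALSE], d[1], d[2], d[3])
    dpv <- ft(dxin[-seq_len(cin_dn), , drop = FALSE], d[1], d[2], d[3])
    back(paste0("pyr", l), dpv)  # pyramid branch ends at the input image
    de <- back(paste0("down", l - 1), ddn)
    if (l > 2) de <- de + d_skip[[l - 1]]
    else de <- de + d_skip[[1]]
  }
  back_lvl("enc1", de)
  grads
}
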