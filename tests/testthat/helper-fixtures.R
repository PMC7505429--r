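# Shared fixtures: a tiny network spec for fast structural tests, and a
# brute-force rasteriser used as the geometric oracle.

tiny_spec <- function(variant = "basic", ...) {
  args <- list(input_size = 32L, encoder_widths = c(4L, 6L, 8L, 10L),
               bottleneck = 12L, pyramid_conv_widths = c(4L, 4L, 4L),
               n_extra_convs = 1L, variant = variant)
  args[names(list(...))] <- list(...)
  do.call(network_spec, args)
}

# filled circle mask by per-pixel membership (independent of the package's
# ellipse rasteriser)
circle_mask <- function(size, center, radius) {
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# random 3-class mask
random_mask <- function(n = 16) {
  matrix(sample(0:2, n * n, replace = TRUE, prob = c(0.6, 0.25, 0.15)), n, n)
}

# brute-force per-pixel contingency oracle
loop_contingency <- function(pred, truth, fg) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] %in% fg
    t <- truth[i, j] %in% fg
    if (p && t) tp <- tp + 1L else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}
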