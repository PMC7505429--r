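## Multi-output cross-entropy loss.
##
## Each of the M = 5 supervised outputs is softmax-normalised over the three
## classes and scored with per-pixel cross entropy against the (resolution-
## matched) label mask; the per-output losses are scaled by fixed weights
## alpha = (0.1, 0.1, 0.1, 0.1, 0.6) and summed.

LOSS_EPS <- 1e-12

#' Cross-entropy loss of one supervised output
#'
#' Computes \eqn{L_i = -(\alpha_i / N) \sum_{pixels} \sum_{classes}
#' y_{o} \log v_{o}} where `y` is the one-hot encoding of `target`, `N` the
#' number of pixels, and probabilities are clamped to `[1e-12, 1]` before the
#' logarithm.
#'
#' @param output H x W x O array of class probabilities (must sum to 1 over
#'   classes at every pixel, tolerance 1e-6).
#' @param target H x W integer mask with values in 0..(O-1).
#' @param alpha nonnegative loss weight for this output.
#' @return nonnegative scalar.
#' @export
per_output_loss <- function(output, target, alpha) {
  if (is.matrix(output)) output <- array(output, c(dim(output), 1L))
  do <- dim(output)
  if (!is.matrix(target) || any(dim(target) != do[1:2]))
    stop("shape mismatch between output and target")
  sums <- apply(output, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop("probabilities are not normalized over classes")
  if (any(target < 0 | target >= do[3]))
    stop("target labels outside 0..", do[3] - 1)
  n <- do[1] * do[2]
  idx <- cbind(as.vector(row(target)), as.vector(col(target)),
               as.vector(target) + 1L)
  v <- pmax(output[idx], LOSS_EPS)
  -(alpha / n) * sum(log(v))
}

#' Total multi-output loss
#'
#' Sum of [per_output_loss()] over the M supervised outputs.
#'
#' @param outputs list of M probability arrays.
#' @param targets list of M label masks at matching resolutions.
#' @param alpha numeric vector of M loss weights.
#' @export
total_loss <- function(outputs, targets, alpha) {
  if (length(outputs) != length(targets) || length(outputs) != length(alpha))
    stop("outputs, targets and alpha must have equal length")
  sum(mapply(per_output_loss, outputs, targets, alpha))
}

## Softmax over the class dimension of a logits tensor (O x P matrix).
softmax_cols <- function(z) {
  m <- z[1, ]
  for (o in 2:nrow(z)) m <- pmax(m, z[o, ])
  e <- exp(z - rep(m, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

## Loss + gradient for one logit head during training.
## logits: O x (H*W*N) tensor; target_ids: integer vector (0-based classes)
## of length H*W*N. Returns loss (already alpha/N-scaled, averaged over the
## batch) and dlogits.
softmax_ce <- function(logits, target_ids, alpha) {
  p <- softmax_cols(logits)
  d <- ft_dims(logits)
  n_batch <- d[3]
  npix <- ncol(logits) / n_batch
  sel <- cbind(target_ids + 1L, seq_along(target_ids))
  loss <- -(alpha / npix) * sum(log(pmax(p[sel], LOSS_EPS))) / n_batch
  y <- matrix(0, nrow(p), ncol(p))
  y[sel] <- 1
  dlogits <- (alpha / (npix * n_batch)) * (p - y)
  list(loss = loss, dlogits = ft(dlogits, d[1], d[2], n_batch))
}
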