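#' Reference 2-D convolution ("same" zero padding)
#'
#' Plain R convolution used by [rcl_forward()] and as an independent check of
#' the C++ engine in the tests. `x` is an H x W x Cin array (a matrix is
#' treated as Cin = 1); `kernel` is kh x kw x Cin x Cout with odd kh, kw.
#'
#' @param x input array.
#' @param kernel kernel array.
#' @return H x W x Cout array.
#' @export
conv2d_ref <- function(x, kernel) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  kd <- dim(kernel)
  if (length(kd) == 2L) kernel <- array(kernel, c(kd, 1L, 1L))
  kd <- dim(kernel)
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  if (kd[3] != cin) stop("channel mismatch")
  hr <- (kd[1] - 1L) %/% 2L; hc <- (kd[2] - 1L) %/% 2L
  out <- array(0, c(H, W, kd[4]))
  for (o in seq_len(kd[4])) {
    acc <- matrix(0, H, W)
    for (ci in seq_len(cin)) {
      for (dr in seq_len(kd[1])) {
        for (dc in seq_len(kd[2])) {
          sr <- (1:H) + (dr - 1L - hr)
          sc <- (1:W) + (dc - 1L - hc)
          vr <- sr >= 1L & sr <= H
          vc <- sc >= 1L & sc <= W
          if (!any(vr) || !any(vc)) next
          acc[vr, vc] <- acc[vr, vc] +
            kernel[dr, dc, ci, o] * x[sr[vr], sc[vc], ci]
        }
      }
    }
    out[, , o] <- acc
  }
  out
}

#' Recurrent convolutional layer (reference recurrence)
#'
#' Iterates the recurrent convolution
#' \deqn{y(t) = \mathrm{ReLU}\big(\mathrm{conv}(x; W^x) +
#'   \mathrm{conv}(y(t-1); W^r) + b\big)}
#' for `t = 0..t_steps`, with the recurrent term absent at `t = 0`. The same
#' feedforward kernel `Wx` and recurrent kernel `Wr` are used at every step
#' (weight sharing across time), so recurrence adds no kernel parameters.
#'
#' @param x input, H x W x Cin array (matrix means Cin = 1).
#' @param weights list with `Wx` (kh x kw x Cin x Cout), `Wr`
#'   (kh x kw x Cout x Cout), and `b` (length Cout; defaults to 0).
#' @param t_steps number of recurrent iterations (>= 0).
#' @return H x W x Cout array: y(t_steps).
#' @export
rcl_forward <- function(x, weights, t_steps = 2L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (t_steps < 0L) stop("t_steps must be >= 0")
  Wx <- weights$Wx; Wr <- weights$Wr
  if (length(dim(Wx)) != 4L) stop("Wx must be a 4-d array")
  if (dim(Wx)[3] != dim(x)[3]) stop("channel mismatch")
  cout <- dim(Wx)[4]
  b <- if (is.null(weights$b)) rep(0, cout) else weights$b
  f <- conv2d_ref(x, Wx)
  y <- pmax(f + rep(b, each = dim(x)[1] * dim(x)[2]), 0)
  dim(y) <- dim(f)
  if (t_steps > 0L) {
    for (t in seq_len(t_steps)) {
      z <- f + conv2d_ref(y, Wr) + rep(b, each = dim(x)[1] * dim(x)[2])
      y <- pmax(z, 0)
      dim(y) <- dim(f)
    }
  }
  y
}
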