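## Polar-coordinate preprocessing.
##
## The fundus crop is resampled about the optic-disc centre onto a
## (theta, r) raster: x = r*cos(theta), y = r*sin(theta) relative to the
## centre, with theta = 0 along the +x (column) axis and increasing
## counter-clockwise in (x, y). This turns the nested disc/cup geometry into
## a layered structure and enlarges the optic cup's pixel share, which is a
## few percent of a disc-centred crop in cartesian coordinates.

#' Polar transform configuration
#'
#' @param center disc centre as `c(row, col)` in pixels (1-based, pixel
#'   centres on integers).
#' @param max_radius largest sampled radius in pixels (> 0).
#' @param n_theta number of angular samples (rows of the polar raster).
#' @param n_radius number of radial samples (columns of the polar raster).
#' @return an object of class `polar_config`.
#' @export
polar_config <- function(center, max_radius, n_theta = 512L, n_radius = 512L) {
  if (max_radius <= 0) stop("max_radius must be > 0")
  if (n_theta < 4L || n_radius < 4L) stop("n_theta and n_radius must be >= 4")
  cfg <- list(center = as.numeric(center), max_radius = as.numeric(max_radius),
              n_theta = as.integer(n_theta), n_radius = as.integer(n_radius))
  class(cfg) <- "polar_config"
  cfg
}

check_center <- function(cfg, dims) {
  if (cfg$center[1] < 1 || cfg$center[1] > dims[1] ||
      cfg$center[2] < 1 || cfg$center[2] > dims[2])
    stop("center out of bounds")
}

apply_channels <- function(image, fun) {
  if (is.matrix(image)) return(fun(image))
  if (length(dim(image)) != 3L) stop("input must be 2-D (per channel)")
  out <- lapply(seq_len(dim(image)[3]), function(k) fun(image[, , k]))
  array(unlist(out), c(dim(out[[1]]), length(out)))
}

#' Cartesian to polar resampling
#'
#' Inverse warping: polar output pixel (i, j) samples the cartesian source at
#' radius r = (j - 0.5) * max_radius / n_radius and angle
#' theta = 2*pi*(i - 1)/n_theta. Intensity images are sampled bilinearly,
#' label masks with nearest neighbour; samples outside the source are 0.
#'
#' @param image matrix or H x W x C array.
#' @param cfg a [polar_config()].
#' @param label TRUE for label masks (nearest-neighbour sampling).
#' @return n_theta x n_radius matrix (or array with C channels).
#' @export
to_polar <- function(image, cfg, label = FALSE) {
  if (!is.matrix(image) && length(dim(image)) != 3L)
    stop("input must be 2-D (per channel)")
  dims <- dim(image)[1:2]
  check_center(cfg, dims)
  th <- 2 * pi * (seq_len(cfg$n_theta) - 1) / cfg$n_theta
  r <- (seq_len(cfg$n_radius) - 0.5) * cfg$max_radius / cfg$n_radius
  qr <- cfg$center[1] + outer(sin(th), r) - 1  # 0-based query rows
  qc <- cfg$center[2] + outer(cos(th), r) - 1
  method <- if (label) 1L else 0L
  apply_channels(image, function(m) {
    matrix(.cpp_warp_sample(m, as.vector(qr), as.vector(qc), method, 0),
           cfg$n_theta, cfg$n_radius)
  })
}

#' Polar to cartesian resampling (inverse transform)
#'
#' Each cartesian output pixel at radius r <= max_radius from the centre
#' samples the polar raster (bilinear with angular wrap-around for images,
#' nearest for masks); pixels beyond max_radius are background 0.
#'
#' @param polar n_theta x n_radius matrix (or array with channels).
#' @param cfg the [polar_config()] used by [to_polar()].
#' @param out_shape `c(rows, cols)` of the cartesian output.
#' @param label TRUE for label masks.
#' @export
from_polar <- function(polar, cfg, out_shape, label = FALSE) {
  pd <- if (is.matrix(polar)) dim(polar) else dim(polar)[1:2]
  if (pd[1] != cfg$n_theta || pd[2] != cfg$n_radius)
    stop("polar grid shape does not match config")
  rows <- matrix(seq_len(out_shape[1]), out_shape[1], out_shape[2])
  cols <- matrix(seq_len(out_shape[2]), out_shape[1], out_shape[2], byrow = TRUE)
  dy <- rows - cfg$center[1]
  dx <- cols - cfg$center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  qi <- th / (2 * pi) * cfg$n_theta        # 0-based fractional theta row
  qj <- pmin(r / cfg$max_radius * cfg$n_radius - 0.5,
             cfg$n_radius - 0.5 - 1e-9)
  outside <- r > cfg$max_radius
  method <- if (label) 1L else 0L
  apply_channels(polar, function(m) {
    # pad one wrapped row at each side so bilinear sampling crosses 2*pi
    mp <- rbind(m[cfg$n_theta, , drop = FALSE], m, m[1, , drop = FALSE])
    v <- .cpp_warp_sample(mp, as.vector(qi) + 1, as.vector(qj), method, 0)
    v[as.vector(outside)] <- 0
    matrix(v, out_shape[1], out_shape[2])
  })
}

#' Optic-cup pixel fraction after polar transform
#'
#' Fraction of pixels labelled 2 (optic cup) in the polar-transformed mask;
#' the class-balance diagnostic motivating the polar preprocessing. For a
#' centred circular cup of radius rho this equals rho / max_radius, always
#' at least the cartesian fraction pi * rho^2 / area.
#'
#' @param mask 3-class label mask (values 0, 1, 2).
#' @param cfg a [polar_config()].
#' @return fraction in `[0, 1]`.
#' @export
polar_cup_fraction <- function(mask, cfg) {
  if (!all(mask %in% 0:2)) stop("mask must be a 3-class label mask")
  mean(to_polar(mask, cfg, label = TRUE) == 2)
}
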