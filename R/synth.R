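## Seeded synthetic disc-centred fundus crops with 3-class ground truth.
##
## The generator emulates the statistical structure the segmentation method
## assumes: a textured reddish background with a smooth illumination
## gradient and dark vessel strokes, a bright elliptical optic disc near the
## crop centre, and a brighter, smaller cup ellipse nested inside it. The
## cup occupies a few percent of the crop (band 2-8%), reproducing the class
## imbalance that motivates the polar transform.

#' Synthetic generator parameters
#'
#' Ellipse-size, intensity, noise and vessel settings for
#' [generate_sample()]. The defaults put the median cup fraction of
#' 512-pixel crops in the 2-8% band and order intensities
#' cup > rim > background in every channel.
#'
#' @param disc_radius_frac range of the disc semi-major axis as a fraction
#'   of the crop side.
#' @param disc_aspect range of the minor/major axis ratio.
#' @param cup_scale range of the cup/disc axis scale (< 1).
#' @param center_jitter_frac disc-centre jitter as a fraction of the side.
#' @param cup_jitter_frac cup-centre jitter as a fraction of the headroom
#'   left by `cup_scale` (containment-safe).
#' @param intensity list of RGB base colours for `bg`, `disc`, `cup`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param n_vessels number of dark vessel polylines.
#' @param vessel_contrast vessel darkening amplitude.
#' @param edge_soft_frac softness of ellipse edges in the rendered image.
#' @export
synth_params <- function(disc_radius_frac = c(0.20, 0.27),
                         disc_aspect = c(0.85, 1.0),
                         cup_scale = c(0.45, 0.58),
                         center_jitter_frac = 0.02,
                         cup_jitter_frac = 0.25,
                         intensity = list(bg = c(0.45, 0.25, 0.12),
                                          disc = c(0.85, 0.72, 0.42),
                                          cup = c(0.97, 0.88, 0.60)),
                         noise_sd = 0.02,
                         n_vessels = 4L,
                         vessel_contrast = 0.12,
                         edge_soft_frac = 0.01) {
  list(disc_radius_frac = disc_radius_frac, disc_aspect = disc_aspect,
       cup_scale = cup_scale, center_jitter_frac = center_jitter_frac,
       cup_jitter_frac = cup_jitter_frac, intensity = intensity,
       noise_sd = noise_sd, n_vessels = as.integer(n_vessels),
       vessel_contrast = vessel_contrast, edge_soft_frac = edge_soft_frac)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

## Squared elliptical metric: <=1 inside the ellipse.
ellipse_q <- function(rows, cols, center, a, b, phi) {
  dx <- cols - center[2]
  dy <- rows - center[1]
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  (u / a)^2 + (v / b)^2
}

#' Generate one synthetic fundus-like sample
#'
#' Deterministic per seed: the same seed yields a bit-identical image and
#' mask. Intensity ordering is cup > disc rim > background in every channel.
#'
#' @param seed integer seed.
#' @param size crop side length (divisible by 16 for direct network use).
#' @param params generator parameters from `synth_params()`.
#' @return list of class `synthetic_sample`: `image` (size x size x 3 in
#'   `[0,1]`), `mask` (size x size, values 0/1/2), `disc_center` (row, col),
#'   `disc_ellipse`, `cup_ellipse` (generating parameters), `seed`.
#' @export
generate_sample <- function(seed, size = 512L, params = synth_params()) {
  if (max(params$cup_scale) >= 1)
    stop("cup cannot fit inside disc: cup_scale must be < 1")
  with_seed(seed, {
    S <- as.integer(size)
    rows <- matrix(seq_len(S), S, S)
    cols <- matrix(seq_len(S), S, S, byrow = TRUE)

    ctr <- (S + 1) / 2 + stats::runif(2, -1, 1) * params$center_jitter_frac * S
    a <- stats::runif(1, params$disc_radius_frac[1], params$disc_radius_frac[2]) * S
    b <- a * stats::runif(1, params$disc_aspect[1], params$disc_aspect[2])
    phi <- stats::runif(1, 0, pi)
    sc <- stats::runif(1, params$cup_scale[1], params$cup_scale[2])
    # cup centre jitter bounded so the cup stays strictly inside the disc
    jmax <- params$cup_jitter_frac * (1 - sc) * min(a, b)
    cctr <- ctr + stats::runif(2, -1, 1) * jmax
    ca <- sc * a; cb <- sc * b

    qd <- ellipse_q(rows, cols, ctr, a, b, phi)
    qc <- ellipse_q(rows, cols, cctr, ca, cb, phi)
    mask <- matrix(0L, S, S)
    mask[qd <= 1] <- 1L
    mask[qc <= 1] <- 2L

    # smooth memberships for the image (soft edges), sharp labels for truth
    soft <- function(q, w) pmin(pmax((1 - q) / w + 0.5, 0), 1)
    w_edge <- max(params$edge_soft_frac, 2 / S) * 8
    md <- soft(qd, w_edge)
    mc <- soft(qc, w_edge)

    grad <- (stats::runif(1, -1, 1) * (cols - S / 2) +
             stats::runif(1, -1, 1) * (rows - S / 2)) / S * 0.08
    img <- array(0, c(S, S, 3))
    for (k in 1:3) {
      base <- params$intensity$bg[k] + grad
      lay <- base * (1 - md) + params$intensity$disc[k] * md
      lay <- lay * (1 - mc) + params$intensity$cup[k] * mc
      img[, , k] <- lay
    }

    # dark vessel polylines converging on the disc
    if (params$n_vessels > 0) {
      vmask <- matrix(0, S, S)
      for (v in seq_len(params$n_vessels)) {
        ang <- stats::runif(1, 0, 2 * pi)
        p0 <- c(S / 2 + sin(ang) * S * 0.7, S / 2 + cos(ang) * S * 0.7)
        p1 <- ctr + stats::runif(2, -1, 1) * 0.15 * S
        nseg <- 6L
        pts <- sapply(seq(0, 1, length.out = nseg + 1), function(t)
          p0 + t * (p1 - p0) + stats::rnorm(2, 0, S * 0.015))
        width <- stats::runif(1, 1.5, 3) * S / 512
        for (sgi in seq_len(nseg)) {
          aa <- pts[, sgi]; bb <- pts[, sgi + 1]
          len <- sqrt(sum((bb - aa)^2))
          tt <- seq(0, 1, length.out = max(2L, ceiling(len)))
          pr <- round(aa[1] + tt * (bb[1] - aa[1]))
          pc <- round(aa[2] + tt * (bb[2] - aa[2]))
          rad <- ceiling(width)
          for (dr in -rad:rad) for (dc in -rad:rad) {
            if (dr * dr + dc * dc > width * width) next
            rr <- pr + dr; cc <- pc + dc
            ok <- rr >= 1 & rr <= S & cc >= 1 & cc <= S
            vmask[cbind(rr[ok], cc[ok])] <- 1
          }
        }
      }
      for (k in 1:3)
        img[, , k] <- img[, , k] - params$vessel_contrast * vmask *
          (1 - 0.7 * mc)  # vessels fade over the bright cup
    }

    if (params$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(S, S, 3L)

    structure(list(image = img, mask = mask, disc_center = ctr,
                   disc_ellipse = list(center = ctr, a = a, b = b, phi = phi),
                   cup_ellipse = list(center = cctr, a = ca, b = cb, phi = phi),
                   seed = seed),
              class = "synthetic_sample")
  })
}

#' Fraction of pixels labelled optic cup
#' @param mask 3-class label mask.
#' @export
cup_fraction <- function(mask) mean(mask == 2)

## Geometric warp of image+mask by an affine map (used for rotation).
warp_pair <- function(image, mask, qr, qc, out_dim) {
  img <- apply_channels(image, function(m)
    matrix(.cpp_warp_sample(m, qr, qc, 0L, 0), out_dim[1], out_dim[2]))
  mk <- matrix(as.integer(.cpp_warp_sample(mask + 0, qr, qc, 1L, 0)),
               out_dim[1], out_dim[2])
  list(image = img, mask = mk)
}

#' Randomly augment a synthetic sample
#'
#' Seeded augmentation: horizontal flip (p = 0.5), vertical flip (p = 0.5),
#' rotation uniform in `[0, 360)` degrees (bilinear image / nearest mask),
#' and a random crop back to the original size after zero-padding `pad`
#' pixels on every side. The identical geometric transform is applied to the
#' image, the mask, and the disc centre. Individual steps can be forced via
#' `hflip`, `vflip`, `angle` (degrees), `crop_offset` (0-based row/col of
#' the crop origin within the padded frame, `c(pad, pad)` = centred).
#'
#' @param sample a `synthetic_sample`.
#' @param seed integer seed.
#' @param pad padding in pixels before the random crop.
#' @param hflip,vflip,angle,crop_offset optional forced transform values.
#' @return augmented `synthetic_sample`.
#' @export
augment_sample <- function(sample, seed, pad = 64L, hflip = NULL, vflip = NULL,
                           angle = NULL, crop_offset = NULL) {
  with_seed(seed, {
    if (is.null(hflip)) hflip <- stats::runif(1) < 0.5
    if (is.null(vflip)) vflip <- stats::runif(1) < 0.5
    if (is.null(angle)) angle <- stats::runif(1, 0, 360)
    S <- nrow(sample$mask)
    if (is.null(crop_offset))
      crop_offset <- c(sample.int(2L * pad + 1L, 1L),
                       sample.int(2L * pad + 1L, 1L)) - 1L

    img <- sample$image; mk <- sample$mask; ctr <- sample$disc_center
    if (hflip) {  # mirror columns
      img <- img[, S:1, , drop = FALSE]
      mk <- mk[, S:1, drop = FALSE]
      ctr[2] <- S + 1 - ctr[2]
    }
    if (vflip) {
      img <- img[S:1, , , drop = FALSE]
      mk <- mk[S:1, , drop = FALSE]
      ctr[1] <- S + 1 - ctr[1]
    }
    if (angle %% 360 != 0) {
      th <- angle * pi / 180
      cc <- (S + 1) / 2
      rows <- matrix(seq_len(S), S, S)
      cols <- matrix(seq_len(S), S, S, byrow = TRUE)
      # inverse rotation of the output grid
      dy <- rows - cc; dx <- cols - cc
      qr <- cc + (-sin(-th) * dx + cos(-th) * dy) - 1
      qc <- cc + (cos(-th) * dx + sin(-th) * dy) - 1
      wp <- warp_pair(img, mk, as.vector(qr), as.vector(qc), c(S, S))
      img <- wp$image; mk <- wp$mask
      d <- c(ctr[1] - cc, ctr[2] - cc)  # (row, col) offset of the disc centre
      ctr <- c(cc - sin(th) * d[2] + cos(th) * d[1],
               cc + cos(th) * d[2] + sin(th) * d[1])
    }
    # pad and crop
    r0 <- crop_offset[1]; c0 <- crop_offset[2]
    rows <- seq_len(S) + r0 - pad
    colsv <- seq_len(S) + c0 - pad
    ok_r <- rows >= 1 & rows <= S
    ok_c <- colsv >= 1 & colsv <= S
    img2 <- array(0, c(S, S, 3))
    mk2 <- matrix(0L, S, S)
    img2[ok_r, ok_c, ] <- img[rows[ok_r], colsv[ok_c], , drop = FALSE]
    mk2[ok_r, ok_c] <- mk[rows[ok_r], colsv[ok_c]]
    ctr <- ctr - c(r0 - pad, c0 - pad)

    structure(list(image = img2, mask = mk2, disc_center = ctr,
                   disc_ellipse = NULL, cup_ellipse = NULL,
                   seed = sample$seed),
              class = "synthetic_sample")
  })
}

#' Multi-size crop expansion
#'
#' Takes centre crops of the requested sizes around the disc centre and
#' rescales each crop (bilinear image, nearest mask) to `out_size`. Crops
#' that do not fit inside the source are skipped with a warning.
#'
#' @param sample a `synthetic_sample`.
#' @param sizes vector of crop side lengths in pixels.
#' @param out_size output side length (default: the sample's own size).
#' @return list of `synthetic_sample` objects.
#' @export
multi_crop_expand <- function(sample, sizes, out_size = nrow(sample$mask)) {
  S <- nrow(sample$mask)
  ctr <- sample$disc_center
  out <- list()
  for (sz in sizes) {
    half <- sz / 2
    r1 <- round(ctr[1] - half + 0.5); r2 <- r1 + sz - 1
    c1 <- round(ctr[2] - half + 0.5); c2 <- c1 + sz - 1
    if (r1 < 1 || c1 < 1 || r2 > S || c2 > S) {
      warning("crop size ", sz, " exceeds source extent; skipped")
      next
    }
    sc <- sz / out_size
    # sample the source at crop coordinates mapped onto the output grid
    g <- (seq_len(out_size) - 0.5) * sc + 0.5
    qr <- matrix(r1 - 1 + g - 1, out_size, out_size)
    qc <- matrix(c1 - 1 + g - 1, out_size, out_size, byrow = TRUE)
    wp <- warp_pair(sample$image, sample$mask, as.vector(qr), as.vector(qc),
                    c(out_size, out_size))
    newc <- c((ctr[1] - r1 + 1) / sc, (ctr[2] - c1 + 1) / sc)
    out[[length(out) + 1]] <-
      structure(list(image = wp$image, mask = wp$mask, disc_center = newc,
                     disc_ellipse = NULL, cup_ellipse = NULL,
                     seed = sample$seed),
                class = "synthetic_sample")
  }
  out
}

#' Generate a seeded dataset of synthetic samples
#'
#' @param n number of samples.
#' @param seed master seed; sample i uses seed `seed + i`.
#' @param size crop side length.
#' @param params generator parameters.
#' @export
generate_dataset <- function(n, seed, size = 64L, params = synth_params()) {
  lapply(seq_len(n), function(i) generate_sample(seed + i, size, params))
}

#' Write a dataset to disk (PNG images/masks + manifest.csv)
#'
#' @param samples list of `synthetic_sample` objects.
#' @param dir output directory (`images/`, `masks/`, `manifest.csv`).
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fn <- sprintf("sample_%04d.png", i)
    png::writePNG(s$image, file.path(dir, "images", fn))
    png::writePNG(s$mask / 255, file.path(dir, "masks", fn))
    data.frame(filename = fn, seed = s$seed,
               center_row = s$disc_center[1], center_col = s$disc_center[2],
               cup_fraction = cup_fraction(s$mask))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    fn <- manifest$filename[i]
    img <- png::readPNG(file.path(dir, "images", fn))
    mk <- round(png::readPNG(file.path(dir, "masks", fn)) * 255)
    structure(list(image = img, mask = matrix(as.integer(mk), nrow(mk)),
                   disc_center = c(manifest$center_row[i], manifest$center_col[i]),
                   disc_ellipse = NULL, cup_ellipse = NULL,
                   seed = manifest$seed[i]),
              class = "synthetic_sample")
  })
}
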