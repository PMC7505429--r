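test_that("generation is bit-identical for the same seed", {
  a <- generate_sample(123, 64)
  b <- generate_sample(123, 64)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_sample(124, 64)
  expect_false(identical(a$mask, c$mask))
})

test_that("every cup pixel lies inside the generating disc ellipse", {
  for (seed in 1:10) {
    s <- generate_sample(seed, 96)
    d <- s$disc_ellipse
    cup <- which(s$mask == 2L, arr.ind = TRUE)
    q <- rfcnet:::ellipse_q(cup[, 1], cup[, 2], d$center, d$a, d$b, d$phi)
    expect_true(all(q <= 1))
    expect_true(all(s$mask %in% 0:2))
  }
})

test_that("intensity ordering is cup > rim > background without noise", {
  p <- synth_params(noise_sd = 0, n_vessels = 0L)
  s <- generate_sample(7, 128, p)
  for (k in 1:3) {
    ch <- s$image[, , k]
    expect_gt(mean(ch[s$mask == 2]), mean(ch[s$mask == 1]))
    expect_gt(mean(ch[s$mask == 1]), mean(ch[s$mask == 0]))
  }
})

test_that("cup parameters that cannot fit inside the disc are rejected", {
  expect_error(generate_sample(1, 64, synth_params(cup_scale = c(1.0, 1.2))),
               "cup cannot fit")
})

test_that("the cup occupies a few percent of 512-pixel crops (median in 2-8%)", {
  fr <- vapply(1:100, function(i) cup_fraction(generate_sample(i, 512)$mask), 0)
  expect_gte(median(fr), 0.02)
  expect_lte(median(fr), 0.08)
})

test_that("augmentation preserves the label alphabet and flip pixel counts", {
  s <- generate_sample(5, 64)
  for (seed in 1:20) {
    a <- augment_sample(s, seed)
    expect_true(all(a$mask %in% 0:2))
  }
  # flips alone change no label counts
  fl <- augment_sample(s, 1, hflip = TRUE, vflip = TRUE, angle = 0,
                       crop_offset = c(64, 64))
  expect_identical(as.vector(table(factor(fl$mask, 0:2))),
                   as.vector(table(factor(s$mask, 0:2))))
  # nearest-neighbour rotation moves label counts by < 15%
  rot <- augment_sample(s, 1, hflip = FALSE, vflip = FALSE, angle = 37,
                        crop_offset = c(64, 64))
  for (l in 1:2) {
    n0 <- sum(s$mask == l); n1 <- sum(rot$mask == l)
    expect_lt(abs(n1 - n0) / n0, 0.15)
  }
})

test_that("the identity augmentation configuration returns the original sample", {
  s <- generate_sample(9, 64)
  a <- augment_sample(s, 3, hflip = FALSE, vflip = FALSE, angle = 0,
                      crop_offset = c(64, 64))
  expect_equal(a$image, s$image, tolerance = 1e-12)
  expect_identical(a$mask, s$mask)
  expect_equal(a$disc_center, s$disc_center)
})

test_that("augmentation keeps the disc centre aligned with the disc region", {
  # rotations and flips with a centred crop keep the full disc visible, so
  # the transformed centre must track the disc-region centroid
  s <- generate_sample(11, 64)
  set.seed(71)
  for (i in 1:10) {
    a <- augment_sample(s, i, hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
                        angle = runif(1, 0, 360), crop_offset = c(64, 64))
    disc <- a$mask >= 1
    centroid <- c(mean(row(a$mask)[disc]), mean(col(a$mask)[disc]))
    expect_lt(sqrt(sum((centroid - a$disc_center)^2)), 4)
  }
})

test_that("cup containment inside the disc survives augmentation", {
  # every cup pixel must have its 8-neighbourhood inside the disc-or-cup
  # region except where the crop boundary cuts through
  s <- generate_sample(13, 64)
  for (seed in 1:50) {
    a <- augment_sample(s, seed)
    cup <- which(a$mask == 2L, arr.ind = TRUE)
    if (nrow(cup) == 0) next
    interior <- cup[cup[, 1] > 1 & cup[, 1] < 64 & cup[, 2] > 1 & cup[, 2] < 64,
                    , drop = FALSE]
    bad <- 0L
    for (r in seq_len(nrow(interior))) {
      nb <- a$mask[interior[r, 1] + (-1:1), interior[r, 2] + (-1:1)]
      if (any(nb == 0)) bad <- bad + 1L
    }
    # nearest-neighbour rotation may graze a few boundary pixels, no more
    expect_lte(bad, max(3, 0.02 * nrow(interior)))
  }
})

test_that("multi-crop expansion rescales around the disc centre", {
  s <- generate_sample(17, 256)
  crops <- multi_crop_expand(s, c(96, 128, 192), out_size = 128)
  expect_length(crops, 3)
  for (cr in crops) {
    expect_identical(dim(cr$mask), c(128L, 128L))
    # disc centre maps to the crop centre
    expect_lt(max(abs(cr$disc_center - 64.5)), 1.5)
    expect_true(all(cr$mask %in% 0:2))
  }
  expect_warning(multi_crop_expand(s, c(64, 512)), "exceeds source")
  # tighter crops increase the cup fraction monotonically
  p <- synth_params(noise_sd = 0, n_vessels = 0L)
  s0 <- generate_sample(19, 256, p)
  fr <- vapply(multi_crop_expand(s0, c(192, 144, 96), out_size = 128),
               function(cr) cup_fraction(cr$mask), 0)
  expect_true(all(diff(fr) > 0))
})

test_that("datasets round-trip through PNG files and the manifest", {
  dir <- tempfile("ds")
  samples <- generate_dataset(3, seed = 400, size = 32)
  man <- write_dataset(samples, dir)
  expect_identical(nrow(man), 3L)
  back <- read_dataset(dir)
  expect_length(back, 3)
  expect_identical(back[[1]]$mask, samples[[1]]$mask)
  expect_equal(back[[2]]$image, samples[[2]]$image, tolerance = 1 / 254)
  expect_equal(back[[3]]$disc_center, samples[[3]]$disc_center)
  unlink(dir, recursive = TRUE)
})
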