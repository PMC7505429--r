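test_that("polar_config validates its invariants", {
  expect_error(polar_config(c(10, 10), max_radius = 0), "max_radius")
  expect_error(polar_config(c(10, 10), 5, n_theta = 3), "n_theta")
  cfg <- polar_config(c(100, 1), 5)
  expect_error(to_polar(matrix(0, 64, 64), cfg), "center out of bounds")
  expect_error(to_polar(1:10, polar_config(c(2, 2), 5)), "2-D")
})

test_that("a constant image stays constant under the polar transform", {
  cfg <- polar_config(c(33, 33), 30, 64, 48)
  p <- to_polar(matrix(2.5, 64, 64), cfg)
  expect_equal(dim(p), c(64, 48))
  expect_true(all(abs(p - 2.5) < 1e-12))
})

test_that("the centre pixel fills the innermost polar column at every angle", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 7
  cfg <- polar_config(c(33, 33), 4, n_theta = 32, n_radius = 16)
  p <- to_polar(img, cfg, label = TRUE)
  expect_true(all(p[, 1] == 7))
})

test_that("a centred disc maps to the first ~30% of polar columns", {
  size <- 128
  cfg <- polar_config(c(64.5, 64.5), 60, 128, 128)
  mask <- circle_mask(size, c(64.5, 64.5), 0.3 * 60) + 0
  p <- to_polar(mask, cfg, label = TRUE)
  # every row: foreground occupies the first ~30% of the radial axis
  runlen <- apply(p, 1, function(r) sum(r == 1))
  expect_true(all(abs(runlen / 128 - 0.3) < 0.02))
  # foreground fraction agrees with the brute-force membership fraction
  frac_polar <- mean(p == 1)
  frac_analytic <- 0.3  # r <= 0.3 max_radius <=> first 30% of columns
  expect_lt(abs(frac_polar - frac_analytic), 0.02)
})

test_that("roundtrip through polar coordinates preserves a smooth image", {
  size <- 96
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  img <- 0.5 + 0.4 * sin(r / 9) * cos(c / 11)
  cfg <- polar_config(c(48.5, 48.5), 48, 192, 192)
  back <- from_polar(to_polar(img, cfg), cfg, c(size, size))
  inside <- (r - 48.5)^2 + (c - 48.5)^2 <= (0.9 * 48)^2
  mae <- mean(abs(back[inside] - img[inside]))
  expect_lt(mae / diff(range(img)), 0.02)
})

test_that("from_polar validates shapes and fills beyond max_radius", {
  cfg <- polar_config(c(17, 17), 10, 32, 32)
  expect_error(from_polar(matrix(0, 16, 32), cfg, c(32, 32)), "shape")
  out <- from_polar(matrix(3, 32, 32), cfg, c(33, 33))
  r <- matrix(seq_len(33), 33, 33)
  c <- matrix(seq_len(33), 33, 33, byrow = TRUE)
  far <- sqrt((r - 17)^2 + (c - 17)^2) > 10.5
  expect_true(all(out[far] == 0))
  near <- sqrt((r - 17)^2 + (c - 17)^2) < 9.5
  expect_true(all(abs(out[near] - 3) < 1e-9))
})

test_that("label masks stay in {0,1,2} through both transforms", {
  set.seed(11)
  for (i in 1:5) {
    mk <- random_mask(48)
    cfg <- polar_config(c(24.5, 24.5), 24, 64, 64)
    p <- to_polar(mk, cfg, label = TRUE)
    b <- from_polar(p, cfg, c(48, 48), label = TRUE)
    expect_true(all(p %in% 0:2))
    expect_true(all(b %in% 0:2))
  }
})

test_that("polar transform enlarges the cup fraction as the analytic ratio", {
  size <- 200
  cfg <- polar_config(c(100.5, 100.5), 100, 256, 256)
  rho <- 0.05 * size                       # cup radius = 5% of image width
  mask <- ifelse(circle_mask(size, c(100.5, 100.5), rho), 2L, 0L)
  pf <- polar_cup_fraction(mask, cfg)
  cf <- mean(mask == 2)
  expect_lt(abs(pf - rho / 100), 1.5 / 256)  # rho/max_radius +-1 column
  expect_lt(abs(cf - pi * rho^2 / size^2), 2e-4)  # rasterisation error
  expect_gt(pf, cf)
  expect_equal(polar_cup_fraction(matrix(0L, 64, 64),
                                  polar_config(c(32, 32), 30, 64, 64)), 0)
})

test_that("polar cup fraction >= cartesian for random nested ellipse masks", {
  set.seed(21)
  for (i in 1:20) {
    size <- 128
    ctr <- c(64.5, 64.5) + runif(2, -3, 3)
    a <- runif(1, 10, 35)
    b <- runif(1, 0.8, 1) * a
    sc <- runif(1, 0.3, 0.7)
    r <- matrix(seq_len(size), size, size)
    c <- matrix(seq_len(size), size, size, byrow = TRUE)
    qd <- ((c - ctr[2]) / a)^2 + ((r - ctr[1]) / b)^2
    qc <- ((c - ctr[2]) / (sc * a))^2 + ((r - ctr[1]) / (sc * b))^2
    mask <- matrix(0L, size, size)
    mask[qd <= 1] <- 1L
    mask[qc <= 1] <- 2L
    cfg <- polar_config(ctr, 64, 128, 128)
    expect_gte(polar_cup_fraction(mask, cfg), mean(mask == 2) - 1e-9)
  }
})
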