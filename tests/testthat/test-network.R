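test_that("network_spec validates its invariants", {
  expect_error(network_spec(input_size = 100), "divisible by 16")
  expect_error(network_spec(encoder_widths = c(8, 16)), "length 4")
  expect_error(network_spec(loss_weights = c(1, 1)), "length 5")
  sp <- network_spec()
  expect_identical(sp$pyramid_sizes, c(512L, 256L, 128L, 64L))
  expect_identical(sp$loss_weights, c(0.1, 0.1, 0.1, 0.1, 0.6))
  expect_identical(sp$n_classes, 3L)
})

test_that("parameter counting matches hand counts on minimal layers", {
  # a lone 3x3 conv, 1 -> 1 channel, with bias: 9 weights + 1 bias = 10
  head1 <- rfcnet:::layer_init(rfcnet:::new_head(1L, 1L))
  expect_identical(rfcnet:::layer_n_params(head1), 10L)
  # bias-free conv + BN: 9*cin*cout kernel + 2*cout affine
  cbr <- rfcnet:::layer_init(rfcnet:::new_cbr(2L, 3L))
  expect_identical(rfcnet:::layer_n_params(cbr), 9L * 6L + 6L)
})

test_that("forward pass yields five 3-channel outputs at the pyramid scales", {
  sp <- tiny_spec()
  m <- build_network(sp, seed = 5)
  for (n in 1:2) {
    x <- rfcnet:::ft(matrix(runif(3 * 32 * 32 * n), 3), 32L, 32L, as.integer(n))
    fw <- rfcnet:::net_forward(m, x)
    expect_length(fw$outputs, 5)
    hs <- vapply(fw$outputs, function(o) rfcnet:::ft_dims(o)[1], 0)
    expect_equal(hs, c(4, 8, 16, 32, 32))
    expect_true(all(vapply(fw$outputs, nrow, 0L) == 3L))
    expect_true(all(vapply(fw$outputs, function(o) rfcnet:::ft_dims(o)[3], 0) == n))
  }
})

test_that("the shape contract holds at a proportionally scaled desk size", {
  sp <- desk_spec(variant = "recurrent")
  expect_identical(sp$pyramid_sizes, c(64L, 32L, 16L, 8L))
  m <- build_network(sp, seed = 2)
  x <- rfcnet:::ft(matrix(runif(3 * 64 * 64), 3), 64L, 64L, 1L)
  fw <- rfcnet:::net_forward(m, x)
  expect_equal(vapply(fw$outputs, function(o) rfcnet:::ft_dims(o)[1], 0),
               c(8, 16, 32, 64, 64))
})

test_that("inference is deterministic: two forward passes are bit-identical", {
  m <- build_network(tiny_spec("stack_recurrent"), seed = 9)
  x <- rfcnet:::ft(matrix(runif(3 * 32 * 32), 3), 32L, 32L, 1L)
  f1 <- rfcnet:::net_forward(m, x)$outputs
  f2 <- rfcnet:::net_forward(m, x)$outputs
  for (h in 1:5) expect_identical(f1[[h]], f2[[h]])
})

test_that("parameter totals are invariant to the polar toggle and grow with stacking", {
  n_basic <- count_parameters(build_network(tiny_spec("basic")))
  n_rec <- count_parameters(build_network(tiny_spec("recurrent")))
  n_stack <- count_parameters(build_network(tiny_spec("stack_recurrent")))
  expect_gt(n_rec, n_basic)
  expect_gt(n_stack, n_rec)
})

test_that("one optimiser step decreases the loss for at least 9 of 10 seeds", {
  sp <- tiny_spec()
  ok <- 0L
  for (s in 1:10) {
    ds <- list(generate_sample(700 + s, 32))
    ck <- rfc_train(ds, sp, train_config(lr = 0.05, epochs = 2, seed = s,
                                         lr_scheduler = FALSE,
                                         use_polar = FALSE))
    if (ck$history[2] < ck$history[1]) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
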