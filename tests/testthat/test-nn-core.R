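test_that("pointwise convolution matches hand examples and errors on channel mismatch", {
  x <- feature_map(0, 4, 3, 3)
  x[1, , ] <- 1; x[2, , ] <- 2; x[3, , ] <- 0; x[4, , ] <- 0
  # zero weights annihilate
  expect_equal(pointwise_conv(x, matrix(0, 2, 4)),
               feature_map(0, 2, 3, 3))
  # identity weights reproduce the input
  expect_equal(pointwise_conv(x, diag(4)), x)
  # per-pixel channel vector (1, 2) under rows (1,1) and (0,1) -> (3, 2)
  x2 <- feature_map(0, 2, 2, 2); x2[1, , ] <- 1; x2[2, , ] <- 2
  w <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  y <- pointwise_conv(x2, w)
  expect_true(all(y[1, , ] == 3) && all(y[2, , ] == 2))
  expect_error(pointwise_conv(x2, matrix(0, 2, 3)), "input channels")
})

test_that("pointwise convolution equals the per-pixel matrix product oracle", {
  for (seed in 1:5) {
    x <- rand_fm(3, 4, 4, seed)
    w <- matrix(rnorm(15), 5, 3)
    expect_equal(pointwise_conv(x, w), oracle_pointwise(x, w), tolerance = 1e-12)
  }
})

test_that("depthwise convolution matches closed cases and the correlation oracle", {
  ones <- feature_map(1, 1, 5, 5)
  k1 <- array(1, c(1, 3, 3))
  y <- depthwise_conv(ones, k1)
  expect_equal(y[1, 3, 3], 9)            # all nine taps inside
  expect_equal(y[1, 1, 1], 4)            # corner sees a 2x2 neighborhood
  expect_equal(depthwise_conv(ones, array(0, c(1, 3, 3))),
               feature_map(0, 1, 5, 5))
  # impulse reproduces the kernel around the center (correlation convention)
  imp <- feature_map(0, 1, 5, 5); imp[1, 3, 3] <- 1
  kr <- array(rnorm(9), c(1, 3, 3))
  yi <- depthwise_conv(imp, kr)
  expect_equal(yi[1, 2:4, 2:4], kr[1, 3:1, 3:1], tolerance = 1e-12)
  for (seed in 6:9) {
    x <- rand_fm(3, 5, 5, seed)
    ker <- array(rnorm(27), c(3, 3, 3))
    expect_equal(depthwise_conv(x, ker), oracle_depthwise(x, ker),
                 tolerance = 1e-12)
  }
  expect_error(depthwise_conv(ones, k1, padding = 0), "padding")
})

test_that("conv_param_count follows the bias-free product rule", {
  expect_equal(conv_param_count(64, 2, 1), 128)
  expect_equal(conv_param_count(3, 64, 3), 1728)
  expect_equal(conv_param_count(7, 11, 1), 77)   # pointwise reduces to Cin*Cout
  expect_error(conv_param_count(0, 4, 3), "positive")
})

test_that("depthwise separable factorization saves parameters once C > K^2/(K^2-1)", {
  for (C in c(2, 4, 16, 64, 256)) {
    for (K in c(3, 5, 7)) {
      full <- conv_param_count(C, C, K)
      separable <- C * K^2 + conv_param_count(C, C, 1)
      if (C > K^2 / (K^2 - 1)) expect_gt(full, separable)
    }
  }
})

test_that("2x2 pooling halves the extent and matches the window oracle", {
  const <- feature_map(2.5, 3, 4, 4)
  for (mode in c("max", "average")) {
    y <- downsample_2x2(const, mode)
    expect_equal(dim(y), c(3L, 2L, 2L))
    expect_true(all(y == 2.5))
  }
  spike <- feature_map(0, 1, 4, 4); spike[1, 2, 3] <- 5
  ym <- downsample_2x2(spike, "max")
  expect_equal(ym[1, 1, 2], 5)
  expect_equal(sum(ym), 5)
  x <- rand_fm(2, 6, 6, 21)
  expect_equal(downsample_2x2(x, "average"), oracle_pool(x, "average"),
               tolerance = 1e-12)
  expect_equal(downsample_2x2(x, "max"), oracle_pool(x, "max"),
               tolerance = 1e-12)
  expect_error(downsample_2x2(rand_fm(1, 5, 4), "max"), "even")
})

test_that("bicubic upsampling doubles the extent, preserves constants, and matches the reference interpolator", {
  cm <- feature_map(0.7, 2, 8, 8)
  up <- bicubic_upsample_x2(cm)
  expect_equal(dim(up), c(2L, 16L, 16L))
  expect_equal(max(abs(up - 0.7)), 0, tolerance = 1e-12)
  shp <- bicubic_upsample_x2(rand_fm(1, 64, 64, 1))
  expect_equal(dim(shp), c(1L, 128L, 128L))
  # ramp and random instances against the direct per-pixel evaluation
  ramp <- feature_map(0, 1, 6, 6)
  ramp[1, , ] <- outer(seq_len(6), seq_len(6), function(a, b) a + 0.5 * b)
  expect_equal(bicubic_upsample_x2(ramp), oracle_bicubic_x2(ramp),
               tolerance = 1e-10)
  x <- rand_fm(2, 5, 7, 31)
  expect_equal(bicubic_upsample_x2(x), oracle_bicubic_x2(x), tolerance = 1e-10)
  expect_error(bicubic_upsample_x2(feature_map(1, 1, 1, 4)), "at least 2")
})

test_that("count_parameters is additive, size-independent, and exact on known layers", {
  pw <- conv_params(64, 128, 1, weights = numeric(64 * 128))
  expect_equal(attr(count_parameters(pw), "total"), 8192)
  dw <- conv_params(16, 16, 3, weights = numeric(16 * 9), depthwise = TRUE)
  both <- count_parameters(list(a = pw, b = dw))
  expect_equal(attr(both, "total"), 8192 + 144)
  expect_equal(sum(both$params), attr(both, "total"))
})

test_that("MAC estimation follows weight_count x output area and handles empty models", {
  pw <- conv_params(64, 128, 1, weights = numeric(64 * 128))
  r <- estimate_macs(pw, 16, 16)
  expect_equal(attr(r, "mac_count"), 64 * 128 * 256)
  expect_equal(attr(r, "flop_count"), 2 * 64 * 128 * 256)
  expect_equal(attr(estimate_macs(list(), 16, 16), "mac_count"), 0)
  net <- build_network(network_config(), seed = 1)
  expect_error(estimate_macs(net, 100, 100), "divisible by 16")
})
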