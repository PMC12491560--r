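test_that("channel-wise spatial pooling yields the max/mean descriptor pair", {
  const <- feature_map(3, 4, 5, 5)
  p <- channel_pool_spatial(const)
  expect_equal(dim(p), c(2L, 5L, 5L))
  expect_true(all(p == 3))
  x <- feature_map(0, 4, 3, 3); x[2, , ] <- 2
  p2 <- channel_pool_spatial(x)
  expect_true(all(p2[1, , ] == 2))       # max channel
  expect_true(all(p2[2, , ] == 0.5))     # mean over 4 channels
  xr <- rand_fm(3, 4, 4, 41)
  expect_equal(channel_pool_spatial(xr), oracle_channel_pool(xr),
               tolerance = 1e-12)
})

test_that("spatial attention is sigmoid-bounded and matches the composed oracle", {
  x <- rand_fm(4, 8, 8, 42)
  zero_cfg <- spatial_attention_config(7, weights = numeric(98))
  expect_true(all(spatial_attention(x, zero_cfg) == 0.5))   # sigma(0)
  set.seed(1)
  cfg <- spatial_attention_config(7)
  w <- spatial_attention(x, cfg)
  expect_equal(dim(w), c(1L, 8L, 8L))
  expect_true(all(w > 0 & w < 1))
  # composed brute force: channel pool -> dense conv -> sigmoid
  expected <- plogis(oracle_conv2(oracle_channel_pool(x), cfg$weights))
  expect_equal(w, expected, tolerance = 1e-10)
  expect_error(spatial_attention_config(4), "odd")
})

test_that("global average pooling equals the arithmetic mean oracle", {
  x <- feature_map(4, 2, 3, 3)
  expect_equal(global_avg_pool(x), c(4, 4))
  half <- feature_map(c(rep(0, 1), rep(1, 1)), 1, 4, 4)
  half[1, , ] <- rep(c(0, 1), 8)
  expect_equal(global_avg_pool(half), 0.5)
  xr <- rand_fm(5, 3, 3, 43)
  expect_equal(global_avg_pool(xr),
               vapply(1:5, function(c) mean(xr[c, , ]), numeric(1)),
               tolerance = 1e-12)
})

test_that("adaptive channel kernel size rounds down to odd and clamps at 1", {
  expect_equal(eca_kernel_size(2), 1)    # 1.5 -> 1
  expect_equal(eca_kernel_size(64), 3)   # 4 -> 3
  expect_equal(eca_kernel_size(512), 5)  # 5.5 -> 5
  expect_equal(eca_kernel_size(1), 1)
  expect_equal(eca_kernel_size(256), 5)  # 5 is already odd
})

test_that("channel attention matches the 1-d sliding-window oracle and stays in (0,1)", {
  x <- rand_fm(8, 4, 4, 44)
  # gamma = 1, b = 0 gives the adaptive size k = 3 at C = 8
  zero_cfg <- channel_attention_config(8, gamma = 1, b = 0,
                                       kernel_weights = numeric(3))
  expect_true(all(channel_attention(x, zero_cfg) == 0.5))
  set.seed(2)
  cfg <- channel_attention_config(8, gamma = 1, b = 0)
  a <- channel_attention(x, cfg)
  expect_length(a, 8)
  expect_true(all(a > 0 & a < 1))
  expect_equal(a, plogis(oracle_conv1d(global_avg_pool(x), cfg$weights)),
               tolerance = 1e-12)
  bad <- channel_attention_config(8)       # adaptive size 1 at the defaults
  bad$kernel_size <- 5L; bad$weights <- numeric(5)
  expect_error(channel_attention(x, bad), "does not match")
})

test_that("attention fusion broadcasts, is linear in x, and reduces to identity", {
  x <- rand_fm(2, 2, 2, 45)
  # alpha = 1, beta = 0, unit channel weights -> identity
  expect_equal(fuse_attention(x, c(1, 1), matrix(0.3, 2, 2),
                              fusion_params(alpha = 1, beta = 0)), x)
  expect_equal(fuse_attention(x, c(1, 1), matrix(0.3, 2, 2),
                              fusion_params(alpha = 0, beta = 0)),
               x * 0)
  # hand-evaluated broadcast: gate = 0.5 * ch(c) + 0.5 * 0.5
  y <- fuse_attention(x, c(0.5, 1), matrix(0.5, 2, 2), fusion_params())
  for (c in 1:2) {
    expect_equal(y[c, , ], x[c, , ] * (0.5 * c(0.5, 1)[c] + 0.25),
                 tolerance = 1e-12)
  }
  # linearity in x for fixed weights
  set.seed(3)
  chw <- runif(2); spw <- matrix(runif(4), 2, 2); f <- fusion_params(0.4, 0.7)
  expect_equal(fuse_attention(3 * x, chw, spw, f),
               3 * fuse_attention(x, chw, spw, f), tolerance = 1e-12)
  expect_error(fuse_attention(x, c(1, 2, 3), spw, f), "channels")
})

test_that("attention weight fields on constant inputs are translation invariant", {
  set.seed(6)
  sp_cfg <- spatial_attention_config(7)
  ch_cfg <- channel_attention_config(6)
  x <- feature_map(1.3, 6, 9, 9)
  w <- spatial_attention(x, sp_cfg)
  inner <- w[1, 4:6, 4:6]   # away from the zero-padded border
  expect_true(diff(range(inner)) < 1e-12)
  a <- channel_attention(x, ch_cfg)
  expect_true(all(a > 0 & a < 1))
})

test_that("the batched attention unit costs about a hundred scalars at C = 512", {
  set.seed(8)
  cfg <- ecdf_config(256, 1024, n = 2, attention_enabled = TRUE)
  blk <- ecdf_block(cfg)
  n_sca <- length(blk$params$sca$w_sp) + length(blk$params$sca$w_ch) + 2L
  expect_lte(n_sca, 2 * 7^2 + eca_kernel_size(512) + 2)
  expect_equal(n_sca, 105)
})
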