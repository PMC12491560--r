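test_that("configuration validation enforces the channel arithmetic", {
  expect_error(ecdf_config(3, 64, n = 3), "power of two")
  expect_error(ecdf_config(3, 60, n = 8), "divisible by 2\\*N")
  cfg <- ecdf_config(3, 64, n = 8)
  expect_equal(cfg$c_mid, 8L)
  expect_equal(cfg$c_branch, 4L)
  expect_equal(cfg$n_dw, 3L)
  expect_equal(cfg$c_cat, 32L)
})

test_that("splitting into halves preserves order and inverts under concatenation", {
  x <- rand_fm(4, 3, 3, 51)
  h <- split_halves(x)
  expect_equal(h[[1]], x[1:2, , , drop = FALSE])
  expect_equal(h[[2]], x[3:4, , , drop = FALSE])
  expect_equal(assemble_concat(h[[1]], list(h[[2]]), list()), x)
  x2 <- rand_fm(2, 2, 2, 52)
  h2 <- split_halves(x2)
  expect_equal(dim(h2[[1]])[1], 1L)
  expect_error(split_halves(rand_fm(3, 2, 2)), "halves")
})

test_that("branch cascades run sequentially and have (N-2)/2 stages", {
  half <- rand_fm(4, 6, 6, 53)
  # N = 2: no depthwise stage at all
  expect_length(branch_cascade(half, list()), 0)
  # identity kernels (center 1): every saved map equals the input half
  id_ker <- array(0, c(4, 3, 3)); id_ker[, 2, 2] <- 1
  out <- branch_cascade(half, list(id_ker, id_ker, id_ker))
  expect_length(out, 3)                   # N = 8 -> three saved maps
  for (z in out) expect_equal(z, half, tolerance = 1e-12)
  # sequential semantics: stage 2 sees stage 1's output
  set.seed(54)
  k1 <- array(rnorm(36), c(4, 3, 3)); k2 <- array(rnorm(36), c(4, 3, 3))
  out2 <- branch_cascade(half, list(k1, k2))
  expect_equal(out2[[2]], depthwise_conv(out2[[1]], k2), tolerance = 1e-12)
})

test_that("the concatenation identity (N-2)C/(2N) + C/N = C/2 holds across the N grid", {
  # fixed instances of the identity
  expect_equal(64 + 6 * 32, 256)                       # N = 8, C_out = 512
  cfg <- ecdf_config(16, 128, n = 4)
  expect_equal(cfg$c_mid + 2 * cfg$n_dw * cfg$c_branch, 64)
  for (n in c(2L, 4L, 8L, 16L, 32L)) {
    for (c_out in (2L * n) * c(1L, 2L, 4L, 8L)) {
      cfg <- ecdf_config(8, c_out, n = n)
      expect_equal(cfg$c_mid + 2L * cfg$n_dw * cfg$c_branch, c_out %/% 2L)
      set.seed(1)
      blk <- ecdf_block(cfg)
      y <- ecdf_forward(rand_fm(8, 4, 4, 55), blk)
      expect_equal(dim(y), c(c_out, 4L, 4L))
    }
  }
})

test_that("the forward pass preserves spatial extent for the reference stage shapes", {
  set.seed(56)
  b1 <- ecdf_block(ecdf_config(3, 64, n = 8))
  expect_equal(dim(ecdf_forward(rand_fm(3, 32, 32, 57), b1)), c(64L, 32L, 32L))
  b5 <- ecdf_block(ecdf_config(1024, 512, n = 8))
  expect_equal(dim(ecdf_forward(rand_fm(1024, 4, 4, 58), b5)), c(512L, 4L, 4L))
  # N = 2 degenerates to pointwise -> attention -> pointwise
  b0 <- ecdf_block(ecdf_config(64, 64, n = 2))
  expect_equal(b0$config$n_dw, 0L)
  expect_equal(dim(ecdf_forward(rand_fm(64, 8, 8, 59), b0)), c(64L, 8L, 8L))
  expect_error(ecdf_forward(rand_fm(5, 8, 8), b0), "input channels")
})

test_that("closed-form block parameter count matches the constructed block", {
  # norm-free, attention-off, dense fusion: 24 + 216 + 2048
  cfg <- ecdf_config(3, 64, n = 8, attention_enabled = FALSE,
                     fusion_groups = 1L, norm = "none")
  expect_equal(ecdf_param_count(cfg), 24 + 216 + 2048)
  set.seed(60)
  for (i in 1:20) {
    n <- sample(c(2L, 4L, 8L, 16L), 1)
    c_out <- (2L * n) * sample(1:8, 1)
    cfg <- ecdf_config(sample(1:64, 1), c_out, n = n,
                       attention_enabled = sample(c(TRUE, FALSE), 1),
                       fusion_groups = sample(c(1L, 2L), 1),
                       norm = sample(c("batch", "none"), 1))
    blk <- ecdf_block(cfg)
    expect_equal(ecdf_param_count(cfg), attr(count_parameters(blk), "total"))
  }
})

test_that("block parameters strictly decrease in the compression factor", {
  counts <- vapply(c(2L, 4L, 8L, 16L, 32L), function(n)
    ecdf_param_count(ecdf_config(256, 512, n = n)), numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("with attention off and no normalization the block is linear in its input", {
  set.seed(61)
  blk <- ecdf_block(ecdf_config(4, 32, n = 4, attention_enabled = FALSE,
                                norm = "none"))
  x <- rand_fm(4, 6, 6, 62)
  expect_equal(ecdf_forward(2 * x, blk), 2 * ecdf_forward(x, blk),
               tolerance = 1e-10)
})

test_that("every learnable scalar receives gradient on a random input/target pair", {
  ns <- asNamespace("lmsaunet")
  set.seed(63)
  cfg <- ecdf_config(3, 16, n = 4)
  blk <- ecdf_block(cfg)
  x <- array(rnorm(3 * 8 * 8 * 2), c(3, 8, 8, 2))
  fw <- ns$ecdf_fwd_batch(blk$params, blk$state, cfg, x,
                          training = TRUE, want_cache = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$ecdf_bwd_batch(blk$params, cfg, fw$cache, dy)
  all_nonzero <- function(g) {
    if (is.list(g)) return(all(vapply(g[!vapply(g, is.null, logical(1))],
                                      all_nonzero, logical(1))))
    any(g != 0)
  }
  expect_true(all_nonzero(bw$grads))
})

test_that("block gradients agree with central finite differences", {
  ns <- asNamespace("lmsaunet")
  set.seed(64)
  cfg <- ecdf_config(3, 16, n = 4)
  blk <- ecdf_block(cfg)
  x <- array(runif(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  tgt <- array(rnorm(16 * 6 * 6 * 2), c(16, 6, 6, 2))
  loss_of <- function(p) {
    fw <- ns$ecdf_fwd_batch(p, blk$state, cfg, x, training = TRUE)
    0.5 * sum((fw$y - tgt)^2)
  }
  fw <- ns$ecdf_fwd_batch(blk$params, blk$state, cfg, x,
                          training = TRUE, want_cache = TRUE)
  bw <- ns$ecdf_bwd_batch(blk$params, cfg, fw$cache, fw$y - tgt)
  eps <- 1e-6
  probes <- list(
    list(c("pw_compress"), 3L),
    list(c("bn_compress", "gamma"), 2L),
    list(list("branch1", 1L, "ker"), 5L),
    list(list("sca", "alpha"), 1L),
    list(list("sca", "w_ch"), 1L),
    list(list("sca", "w_sp"), 10L),
    list(list("pw_fuse", 1L), 7L)
  )
  for (pr in probes) {
    path <- as.list(pr[[1]]); j <- pr[[2]]
    leaf <- blk$params; for (k in path) leaf <- leaf[[k]]
    g_leaf <- bw$grads; for (k in path) g_leaf <- g_leaf[[k]]
    bump <- function(delta) {
      p2 <- blk$params
      expr <- leaf; expr[j] <- expr[j] + delta
      # write back along the path
      assign_path <- function(tree, path, val) {
        if (!length(path)) return(val)
        tree[[path[[1]]]] <- assign_path(tree[[path[[1]]]], path[-1], val)
        tree
      }
      assign_path(p2, path, expr)
    }
    g_fd <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    expect_equal(g_leaf[j], g_fd, tolerance = 1e-4)
  }
})
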