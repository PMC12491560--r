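#' Spatial and channel attention configuration
#'
#' The block's attention unit gates the feature map with two multiplicative
#' fields computed in parallel: a per-position spatial weight in (0,1) derived
#' from channel-pooled statistics through a small 2-to-1 convolution, and a
#' per-channel weight in (0,1) derived from globally pooled channel statistics
#' through an adaptively sized 1-d convolution (the efficient-channel-attention
#' design). The two fields are combined with learnable scalars `alpha` and
#' `beta` before being applied to the map.
#'
#' @param kernel_size odd spatial kernel side (default 7, the usual choice for
#'   this style of spatial attention).
#' @param weights optional `1 x 2 x k x k` conv weights; random fan-in-scaled
#'   draws otherwise.
#' @return Configuration objects used by the attention operations.
#' @export
spatial_attention_config <- function(kernel_size = 7L, weights = NULL) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L || kernel_size < 3L) {
    stop("spatial attention kernel must be odd and >= 3; got ", kernel_size,
         call. = FALSE)
  }
  n <- 2L * kernel_size^2
  if (is.null(weights)) weights <- rnorm(n, sd = sqrt(2 / n))
  if (length(weights) != n) {
    stop("spatial attention expects 2*k*k = ", n, " weights", call. = FALSE)
  }
  structure(list(kernel_size = kernel_size,
                 weights = array(as.numeric(weights),
                                 c(1L, 2L, kernel_size, kernel_size))),
            class = "spatial_attention_config")
}

#' @rdname spatial_attention_config
#' @param gamma,b real hyperparameters of the adaptive kernel-size rule
#'   `k = floor_odd(log2(C)/gamma + b)`; defaults 2 and 1 are the standard
#'   efficient-channel-attention settings.
#' @param channels channel count the 1-d kernel must serve.
#' @param kernel_weights optional length-`k` 1-d kernel.
#' @export
channel_attention_config <- function(channels, gamma = 2, b = 1,
                                     kernel_weights = NULL) {
  k <- eca_kernel_size(channels, gamma = gamma, b = b)
  if (is.null(kernel_weights)) kernel_weights <- rnorm(k, sd = sqrt(1 / k))
  if (length(kernel_weights) != k) {
    stop("channel attention kernel must have length ", k, " for C = ", channels,
         call. = FALSE)
  }
  structure(list(channels = as.integer(channels), gamma = gamma, b = b,
                 kernel_size = k, weights = as.numeric(kernel_weights)),
            class = "channel_attention_config")
}

#' @rdname spatial_attention_config
#' @param alpha,beta learnable fusion scalars; both start at 0.5 so neither
#'   field dominates before training.
#' @export
fusion_params <- function(alpha = 0.5, beta = 0.5) {
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "fusion_params")
}

#' Channel-wise spatial pooling
#'
#' Compresses the channel axis at every position into two descriptor
#' channels: the per-pixel maximum over channels and the per-pixel mean,
#' concatenated in that order.
#'
#' @param x a `C x H x W` feature map.
#' @return A `2 x H x W` feature map.
#' @export
channel_pool_spatial <- function(x) {
  check_feature_map(x)
  d <- dim(x)
  r <- cpp_chpool_fwd(as.numeric(x), d[1], d[2], d[3], 1L)
  array(r$out, c(2L, d[2], d[3]))
}

#' Spatial attention weight map
#'
#' Applies the configured `k x k` convolution to the two pooled descriptor
#' channels and squashes the result through a sigmoid, yielding one weight per
#' spatial position, strictly inside (0, 1).
#'
#' @param x a `C x H x W` feature map.
#' @param cfg a [spatial_attention_config()].
#' @return A `1 x H x W` weight map.
#' @export
spatial_attention <- function(x, cfg = spatial_attention_config()) {
  pooled <- channel_pool_spatial(x)
  d <- dim(pooled)
  k <- cfg$kernel_size
  g <- cpp_conv2_fwd(as.numeric(pooled), as.numeric(cfg$weights),
                     2L, 1L, d[2], d[3], 1L, k, k %/% 2L)
  array(plogis(g), c(1L, d[2], d[3]))
}

#' Global average pooling per channel
#'
#' @param x a `C x H x W` feature map.
#' @return Numeric vector of length C with each channel's spatial mean.
#' @export
global_avg_pool <- function(x) {
  check_feature_map(x)
  rowMeans(matrix(x, dim(x)[1]))
}

#' Adaptive 1-d attention kernel size
#'
#' `k = floor_odd(log2(C)/gamma + b)`: the largest odd integer no greater than
#' the value, clamped below at 1, so wider maps get wider channel-interaction
#' kernels without a fully connected layer.
#'
#' @param channels channel count C.
#' @param gamma,b hyperparameters (defaults 2 and 1).
#' @return An odd integer kernel length.
#' @examples
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(512)  # 5
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  stopifnot(channels >= 1)
  v <- log2(channels) / gamma + b
  k <- floor(v)
  if (k %% 2 == 0) k <- k - 1          # round down to the nearest odd
  max(1L, as.integer(k))
}

# zero-padded same-length 1-d correlation of each column of s (C x B)
conv1d_same <- function(s, w) {
  C <- nrow(s); k <- length(w); p <- k %/% 2L
  sp <- rbind(matrix(0, p, ncol(s)), s, matrix(0, p, ncol(s)))
  out <- matrix(0, C, ncol(s))
  for (j in seq_len(k)) out <- out + w[j] * sp[j:(j + C - 1L), , drop = FALSE]
  out
}

#' Channel attention weights
#'
#' Pools each channel to its global mean, runs the length-C vector through a
#' zero-padded 1-d convolution whose kernel size follows
#' [eca_kernel_size()], and maps the result through a sigmoid.
#'
#' @param x a `C x H x W` feature map.
#' @param cfg a [channel_attention_config()] sized for C channels.
#' @return Numeric vector of length C with weights strictly inside (0, 1).
#' @export
channel_attention <- function(x, cfg) {
  check_feature_map(x)
  C <- dim(x)[1]
  if (cfg$kernel_size != eca_kernel_size(C, cfg$gamma, cfg$b)) {
    stop("channel attention kernel length ", cfg$kernel_size,
         " does not match the adaptive size for C = ", C, call. = FALSE)
  }
  s <- matrix(global_avg_pool(x), ncol = 1)
  as.numeric(plogis(conv1d_same(s, cfg$weights)))
}

#' Fuse attention weights into a feature map
#'
#' `out(c,h,w) = x(c,h,w) * (alpha * ch_w(c) + beta * sp_w(h,w))`: the channel
#' vector broadcasts over space, the spatial map over channels, and the
#' learnable scalars set the balance between the two gates.
#'
#' @param x a `C x H x W` feature map.
#' @param ch_w channel weight vector of length C.
#' @param sp_w spatial weight map, `1 x H x W` (or `H x W`).
#' @param f a [fusion_params()].
#' @return A feature map the same shape as `x`.
#' @export
fuse_attention <- function(x, ch_w, sp_w, f = fusion_params()) {
  check_feature_map(x)
  d <- dim(x)
  if (length(ch_w) != d[1]) {
    stop("channel weights have length ", length(ch_w), " but the map has ",
         d[1], " channels", call. = FALSE)
  }
  sp <- if (length(dim(sp_w)) == 3L) sp_w[1, , ] else sp_w
  if (!all(dim(sp) == d[2:3])) {
    stop("spatial weights are ", paste(dim(sp), collapse = " x "),
         " but the map is ", d[2], " x ", d[3], call. = FALSE)
  }
  gate <- f$alpha * as.numeric(ch_w) +
    f$beta * array(rep(as.numeric(sp), each = d[1]), d)
  x * gate
}

# ---- internal batched spatial-channel attention with backward pass ----

# params: list(w_sp = (1,2,ks,ks), w_ch = length-k vector, alpha, beta)
sca_fwd <- function(x, params, want_cache = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  # channel branch: per-sample global average pool -> 1-d conv -> sigmoid
  s <- cpp_gap_fwd(x, C, H * W, B)                  # C x B
  a <- plogis(conv1d_same(s, params$w_ch))          # C x B channel weights
  # spatial branch: channel pooling -> k x k conv -> sigmoid
  cp <- cpp_chpool_fwd(x, C, H, W, B)
  ks <- dim(params$w_sp)[3]
  g <- cpp_conv2_fwd(cp$out, params$w_sp, 2L, 1L, H, W, B, ks, ks %/% 2L)
  sp <- plogis(g)                                   # length H*W*B
  y <- cpp_sca_gate_fwd(x, a, sp, params$alpha, params$beta, C, H * W, B)
  dim(y) <- d
  if (!want_cache) return(list(y = y))
  list(y = y, x = x, s = s, a = a, sp = sp, cp = cp, dims = d)
}

sca_bwd <- function(cache, params, dy) {
  d <- cache$dims; C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  r <- cpp_sca_gate_bwd(cache$x, dy, cache$a, cache$sp,
                        params$alpha, params$beta, C, H * W, B)
  dx <- r$dx
  dim(dx) <- d
  # channel path: through the sigmoid, the 1-d conv, and the global pool
  dt <- params$alpha * r$da * cache$a * (1 - cache$a)
  k <- length(params$w_ch); p <- k %/% 2L
  sp_pad <- rbind(matrix(0, p, B), cache$s, matrix(0, p, B))
  dw_ch <- vapply(seq_len(k), function(j)
    sum(dt * sp_pad[j:(j + C - 1L), , drop = FALSE]), numeric(1))
  ds_pad <- matrix(0, C + 2L * p, B)
  for (j in seq_len(k)) {
    ds_pad[j:(j + C - 1L), ] <- ds_pad[j:(j + C - 1L), ] + params$w_ch[j] * dt
  }
  ds <- ds_pad[(p + 1L):(p + C), , drop = FALSE]
  dx <- cpp_gap_bwd_add(dx, ds, C, H * W, B)
  dim(dx) <- d
  # spatial path: through the sigmoid, the k x k conv, the channel pooling
  dg <- params$beta * r$dsp * cache$sp * (1 - cache$sp)
  ks <- dim(params$w_sp)[3]
  rc <- cpp_conv2_bwd(cache$cp$out, params$w_sp, dg,
                      2L, 1L, H, W, B, ks, ks %/% 2L)
  dx <- dx + cpp_chpool_bwd(rc$dx, cache$cp$arg, C, H, W, B)
  dw_sp <- rc$dw
  dim(dw_sp) <- dim(params$w_sp)
  list(dx = dx,
       grads = list(w_sp = dw_sp, w_ch = dw_ch,
                    alpha = r$dalpha, beta = r$dbeta))
}

# parameter template for one attention unit over C channels
sca_init <- function(channels, spatial_kernel = 7L, gamma = 2, b = 1) {
  sp <- spatial_attention_config(spatial_kernel)
  ch <- channel_attention_config(channels, gamma = gamma, b = b)
  list(w_sp = sp$weights, w_ch = ch$weights, alpha = 0.5, beta = 0.5)
}
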