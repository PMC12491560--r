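#' Convolution parameter bundles
#'
#' Convolution weights are bias-free throughout the network, so a layer is
#' fully described by its weight tensor. A dense (pointwise when `kernel_size
#' = 1`) layer holds `out_channels x in_channels x K x K` weights; a depthwise
#' layer holds one `K x K` kernel per channel (`in_channels = out_channels`).
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size square kernel side K in pixels.
#' @param weights optional numeric weights; when `NULL`, fan-in-scaled normal
#'   draws from the current RNG stream are used.
#' @param depthwise logical; one independent kernel per channel.
#' @return An object of class `conv_params`.
#' @export
conv_params <- function(in_channels, out_channels, kernel_size = 1L,
                        weights = NULL, depthwise = FALSE) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel_size >= 1)
  if (depthwise) {
    if (in_channels != out_channels) {
      stop("depthwise convolution requires in_channels == out_channels (got ",
           in_channels, " and ", out_channels, ")", call. = FALSE)
    }
    n <- in_channels * kernel_size^2
    if (is.null(weights)) {
      weights <- rnorm(n, sd = sqrt(2 / kernel_size^2))
    }
    if (length(weights) != n) {
      stop("depthwise weights must hold C*K*K = ", n, " values", call. = FALSE)
    }
    w <- array(as.numeric(weights), c(in_channels, kernel_size, kernel_size))
  } else {
    n <- in_channels * out_channels * kernel_size^2
    if (is.null(weights)) {
      weights <- rnorm(n, sd = sqrt(2 / (in_channels * kernel_size^2)))
    }
    if (length(weights) != n) {
      stop("dense weights must hold Cin*Cout*K*K = ", n, " values", call. = FALSE)
    }
    w <- array(as.numeric(weights),
               c(out_channels, in_channels, kernel_size, kernel_size))
  }
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         kernel_size = as.integer(kernel_size),
         depthwise = isTRUE(depthwise),
         weights = w),
    class = "conv_params")
}

#' Pointwise (1 x 1) convolution
#'
#' Linearly mixes channels at every spatial location:
#' `y(c_out, h, w) = sum_cin W(c_out, c_in) * x(c_in, h, w)`. The spatial
#' extent is untouched; this is the channel-adjustment primitive used for
#' compression and fusion throughout the network.
#'
#' @param x a `C_in x H x W` feature map.
#' @param p a [conv_params()] with `kernel_size = 1`, or a plain
#'   `C_out x C_in` weight matrix.
#' @return A `C_out x H x W` feature map.
#' @examples
#' x <- feature_map(1, 2, 4, 4)
#' w <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE)
#' y <- pointwise_conv(x, w)
#' @export
pointwise_conv <- function(x, p) {
  check_feature_map(x)
  w <- if (inherits(p, "conv_params")) {
    if (p$kernel_size != 1L) stop("pointwise convolution needs kernel_size 1", call. = FALSE)
    matrix(p$weights, p$out_channels, p$in_channels)
  } else {
    as.matrix(p)
  }
  d <- dim(x)
  if (ncol(w) != d[1]) {
    stop("pointwise weight expects ", ncol(w), " input channels but the map has ",
         d[1], call. = FALSE)
  }
  y <- w %*% matrix(x, d[1])
  array(y, c(nrow(w), d[2], d[3]))
}

#' Depthwise convolution
#'
#' Each channel is correlated with its own `K x K` kernel
#' (`y(c,h,w) = sum_ij W(c,i,j) * x(c, h+i-pad, w+j-pad)`, zero padding,
#' stride 1); no cross-channel mixing takes place. With the default padding
#' `floor(K/2)` the spatial size is preserved.
#'
#' @param x a `C x H x W` feature map.
#' @param p a depthwise [conv_params()], or a `C x K x K` kernel array.
#' @param padding zero-padding width in pixels.
#' @return A feature map with the same channel count.
#' @export
depthwise_conv <- function(x, p, padding = NULL) {
  check_feature_map(x)
  ker <- if (inherits(p, "conv_params")) {
    if (!p$depthwise) stop("expected depthwise conv_params", call. = FALSE)
    p$weights
  } else p
  kd <- dim(ker)
  if (length(kd) != 3L || kd[2] != kd[3]) {
    stop("depthwise kernels must form a C x K x K array", call. = FALSE)
  }
  d <- dim(x)
  if (kd[1] != d[1]) {
    stop("kernel bank has ", kd[1], " channels but the map has ", d[1], call. = FALSE)
  }
  K <- kd[2]
  if (is.null(padding)) padding <- K %/% 2
  if (K > d[2] + 2 * padding || K > d[3] + 2 * padding) {
    stop("kernel of size ", K, " exceeds the padded input extent", call. = FALSE)
  }
  if (2 * padding + 1 != K) {
    stop("only 'same' padding floor(K/2) is supported (got padding ", padding, ")",
         call. = FALSE)
  }
  y <- cpp_dw_fwd(as.numeric(x), as.numeric(ker), d[1], d[2], d[3], 1L, K, padding)
  array(y, d)
}

#' Trainable scalar count of one convolution
#'
#' The bias-free parameter count `Cin * Cout * K * K`; for `k = 1` this is the
#' pointwise count `Cin * Cout`. At the deepest stage of a classical U-Net
#' (1024 channels in and out, 3 x 3 kernels) a single such layer already costs
#' about 9.44 million scalars, which is the budget problem the compressed
#' block design removes.
#'
#' @param c_in,c_out channel counts.
#' @param k square kernel side.
#' @return Integer scalar count.
#' @examples
#' conv_param_count(1024, 1024, 3) / 1e6
#' @export
conv_param_count <- function(c_in, c_out, k = 1L) {
  if (any(c(c_in, c_out, k) < 1)) {
    stop("conv_param_count needs positive channel counts and kernel size", call. = FALSE)
  }
  as.numeric(c_in) * as.numeric(c_out) * as.numeric(k)^2
}

#' 2 x 2 downsampling
#'
#' Halves the spatial extent with non-overlapping 2 x 2 max or average
#' pooling (stride 2). Network inputs are constrained to even extents so the
#' windows always tile exactly.
#'
#' @param x a `C x H x W` feature map with even H and W.
#' @param mode `"max"` or `"average"`.
#' @return A `C x H/2 x W/2` feature map.
#' @export
downsample_2x2 <- function(x, mode = c("max", "average")) {
  mode <- match.arg(mode)
  check_feature_map(x)
  d <- dim(x)
  if (d[2] %% 2L || d[3] %% 2L) {
    stop("2x2 downsampling needs even spatial extents; got ", d[2], " x ", d[3],
         " (constrain inputs to sizes divisible by 16)", call. = FALSE)
  }
  r <- cpp_pool_fwd(as.numeric(x), d[1], d[2], d[3], 1L,
                    if (mode == "max") 0L else 1L)
  array(r$out, c(d[1], d[2] %/% 2L, d[3] %/% 2L))
}

# Keys cubic kernel (a = -1/2), the common bicubic interpolation weight
cubic_weight <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

#' Bicubic 2x upsampling
#'
#' Parameter-free doubling of the spatial extent by bicubic interpolation at
#' half-pixel-aligned sample centers (no corner alignment); the decoder uses
#' this in place of learned transposed convolutions. Constants are reproduced
#' exactly and borders replicate edge samples.
#'
#' @param x a `C x H x W` feature map with `H, W >= 2`.
#' @return A `C x 2H x 2W` feature map.
#' @export
bicubic_upsample_x2 <- function(x) {
  check_feature_map(x)
  d <- dim(x)
  if (d[2] < 2 || d[3] < 2) {
    stop("bicubic upsampling needs at least 2 pixels per axis", call. = FALSE)
  }
  drop_batch(upsample_fwd(as_batch(x)))
}

# ---- internal batched primitives (C,H,W,B), used by the training path ----

pw_fwd <- function(x, w) {
  d <- dim(x)
  y <- cpp_pw_fwd(x, w, d[1])
  dim(y) <- c(nrow(w), d[2], d[3], d[4])
  y
}

pw_bwd <- function(x, w, dy) {
  d <- dim(x)
  r <- cpp_pw_bwd(x, w, dy, d[1])
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dw = r$dw)
}

dw_fwd <- function(x, ker) {
  d <- dim(x); K <- dim(ker)[2]
  y <- cpp_dw_fwd(x, ker, d[1], d[2], d[3], d[4], K, K %/% 2L)
  dim(y) <- d
  y
}

dw_bwd <- function(x, ker, dy) {
  d <- dim(x); K <- dim(ker)[2]
  r <- cpp_dw_bwd(x, ker, dy, d[1], d[2], d[3], d[4], K, K %/% 2L)
  dx <- r$dx; dim(dx) <- d
  dker <- r$dker; dim(dker) <- dim(ker)
  list(dx = dx, dker = dker)
}

pool_fwd <- function(x, mode) {
  d <- dim(x)
  r <- cpp_pool_fwd(x, d[1], d[2], d[3], d[4], if (mode == "max") 0L else 1L)
  y <- r$out
  dim(y) <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4])
  list(y = y, arg = r$arg, dims = d, mode = mode)
}

pool_bwd <- function(cache, dy) {
  d <- cache$dims
  dx <- cpp_pool_bwd(dy, cache$arg, d[1], d[2], d[3], d[4],
                     if (cache$mode == "max") 0L else 1L)
  dim(dx) <- d
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  y <- cpp_upsample2_fwd(x, d[1], d[2], d[3], d[4])
  dim(y) <- c(d[1], 2L * d[2], 2L * d[3], d[4])
  y
}

# adjoint of upsample_fwd (the exact gradient of the linear operator)
upsample_bwd <- function(dy, in_h, in_w) {
  d <- dim(dy)
  dx <- cpp_upsample2_bwd(dy, d[1], in_h, in_w, d[4])
  dim(dx) <- c(d[1], in_h, in_w, d[4])
  dx
}

relu_fwd <- function(x) {
  y <- cpp_relu_fwd(x)
  dim(y) <- dim(x)
  y
}

# `ref` may be the pre-activation or the (non-negative) post-activation map:
# both carry the same positivity pattern almost everywhere
relu_bwd <- function(ref, dy) {
  dx <- cpp_relu_bwd(ref, dy)
  dim(dx) <- dim(dy)
  dx
}

# batch normalization over (H, W, B) per channel
bn_fwd <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  r <- cpp_bn_fwd(x, gamma, beta, rmean, rvar, d[1],
                  if (training) 1L else 0L, eps)
  y <- r$y
  dim(y) <- d
  if (training) {
    rmean <- (1 - momentum) * rmean + momentum * r$mu
    rvar <- (1 - momentum) * rvar + momentum * r$var
  }
  list(y = y, mu = r$mu, invstd = r$invstd, rmean = rmean, rvar = rvar)
}

# x is the layer input that bn_fwd normalized (not the normalized output)
bn_bwd <- function(x, mu, invstd, gamma, dy) {
  d <- dim(dy)
  r <- cpp_bn_bwd(x, mu, invstd, gamma, dy, d[1])
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}
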