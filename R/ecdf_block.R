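#' ECDF block configuration
#'
#' One ECDF (efficient channel-compressed dual-branch depthwise fusion) unit
#' replaces the double 3 x 3 convolution of a classical U-Net stage. A
#' pointwise convolution first compresses the input to `C_out / N` channels
#' (`N = 2^K`, the compression factor); the compressed map is split into two
#' halves of `C_out / (2N)` channels, each of which runs a sequential cascade
#' of `(N - 2) / 2` depthwise convolutions whose every intermediate is kept;
#' the `N - 2` saved maps are concatenated with the compressed map to exactly
#' `C_out / 2` channels (`(N-2) * C_out/(2N) + C_out/N = C_out/2`); parallel
#' spatial-channel attention gates that map; and a final pointwise convolution
#' restores `C_out` channels.
#'
#' @param in_channels,out_channels block input/output channel counts.
#' @param n compression factor, a power of two >= 2; `out_channels` must be
#'   divisible by `2 * n`.
#' @param dw_kernel odd depthwise kernel side (default 3).
#' @param attention_enabled gate the concatenated map with spatial-channel
#'   attention (default TRUE).
#' @param fusion_groups 1 (dense) or 2 (channel-grouped) final pointwise; the
#'   grouped default is what keeps the assembled network under its 0.4 M
#'   parameter budget.
#' @param norm `"batch"` (batch normalization + rectified-linear activation
#'   after the compression and after each depthwise stage) or `"none"`.
#' @param spatial_kernel,gamma,b attention hyperparameters.
#' @return An `ecdf_config` object.
#' @examples
#' cfg <- ecdf_config(3, 64, n = 8)
#' ecdf_param_count(cfg)
#' @export
ecdf_config <- function(in_channels, out_channels, n = 8L, dw_kernel = 3L,
                        attention_enabled = TRUE, fusion_groups = 2L,
                        norm = c("batch", "none"), spatial_kernel = 7L,
                        gamma = 2, b = 1) {
  norm <- match.arg(norm)
  n <- as.integer(n)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("compression factor must be a power of two >= 2; got ", n, call. = FALSE)
  }
  if (out_channels %% (2L * n) != 0L) {
    stop("out_channels (", out_channels, ") must be divisible by 2*N = ",
         2L * n, call. = FALSE)
  }
  if (dw_kernel %% 2L == 0L) stop("depthwise kernel must be odd", call. = FALSE)
  if (!fusion_groups %in% c(1L, 2L)) {
    stop("fusion_groups must be 1 or 2", call. = FALSE)
  }
  structure(list(
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    n = n,
    dw_kernel = as.integer(dw_kernel),
    attention_enabled = isTRUE(attention_enabled),
    fusion_groups = as.integer(fusion_groups),
    norm = norm,
    spatial_kernel = as.integer(spatial_kernel),
    gamma = gamma, b = b,
    c_mid = as.integer(out_channels %/% n),        # compressed width
    c_branch = as.integer(out_channels %/% (2L * n)),
    n_dw = as.integer((n - 2L) %/% 2L),            # depthwise stages per branch
    c_cat = as.integer(out_channels %/% 2L)        # concatenated width
  ), class = "ecdf_config")
}

#' Split a feature map into channel halves
#'
#' @param x a feature map with an even channel count.
#' @return A list of two maps: channels `[1, C/2]` and `[C/2+1, C]`.
#' @export
split_halves <- function(x) {
  check_feature_map(x)
  C <- dim(x)[1]
  if (C %% 2L) stop("cannot split ", C, " channels into halves", call. = FALSE)
  list(x[seq_len(C %/% 2L), , , drop = FALSE],
       x[(C %/% 2L + 1L):C, , , drop = FALSE])
}

#' Cascaded depthwise convolutions over one branch
#'
#' Runs the kernels sequentially -- each consumes the previous output -- and
#' returns every intermediate, so that later concatenation carries
#' progressively larger receptive fields ("multi-level" semantics).
#'
#' @param half one channel half of the compressed map.
#' @param kernels ordered list of depthwise kernel arrays (each
#'   `C x K x K` for this half's channel count); length `(N-2)/2`.
#' @param activation apply a rectified-linear activation after each stage
#'   (default FALSE for the bare functional form; the assembled block uses
#'   batch normalization + activation internally).
#' @return List of feature maps, one per cascade stage, each shaped like
#'   `half`.
#' @export
branch_cascade <- function(half, kernels, activation = FALSE) {
  check_feature_map(half)
  out <- vector("list", length(kernels))
  z <- half
  for (i in seq_along(kernels)) {
    z <- depthwise_conv(z, kernels[[i]])
    if (activation) z <- relu_fwd(z)
    out[[i]] <- z
  }
  out
}

#' Concatenate the compressed map with both branch cascades
#'
#' Channel order is `[compressed, branch 1 stages, branch 2 stages]`; the
#' result always holds `C_out / 2` channels for a valid configuration.
#'
#' @param xp the compressed (`C_out / N` channel) map.
#' @param branch1,branch2 lists of cascade outputs from [branch_cascade()].
#' @return The concatenated feature map.
#' @export
assemble_concat <- function(xp, branch1, branch2) {
  maps <- c(list(xp), branch1, branch2)
  d <- dim(maps[[1]])[2:3]
  for (m in maps) {
    if (!all(dim(m)[2:3] == d)) {
      stop("all maps entering the concatenation must share the spatial extent",
           call. = FALSE)
    }
  }
  ch <- vapply(maps, function(m) dim(m)[1], integer(1))
  out <- array(0, c(sum(ch), d))
  at <- 0L
  for (m in maps) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

# ---- block construction ----

new_bn <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

new_bn_state <- function(channels) {
  list(mean = rep(0, channels), var = rep(1, channels))
}

#' Construct an ECDF block
#'
#' Initializes all learnable tensors of one block (fan-in-scaled normal conv
#' weights from the current RNG stream, unit batch-norm scales, fusion
#' scalars at 0.5) together with its running normalization statistics.
#'
#' @param cfg an [ecdf_config()].
#' @return An `ecdf_block` object holding `config`, `params`, and `state`.
#' @export
ecdf_block <- function(cfg) {
  stopifnot(inherits(cfg, "ecdf_config"))
  K <- cfg$dw_kernel
  branch_kernels <- function() {
    lapply(seq_len(cfg$n_dw), function(i) {
      list(ker = array(rnorm(cfg$c_branch * K * K, sd = sqrt(2 / K^2)),
                       c(cfg$c_branch, K, K)),
           bn = if (cfg$norm == "batch") new_bn(cfg$c_branch))
    })
  }
  g <- cfg$fusion_groups
  params <- list(
    pw_compress = matrix(rnorm(cfg$c_mid * cfg$in_channels,
                               sd = sqrt(2 / cfg$in_channels)),
                         cfg$c_mid, cfg$in_channels),
    bn_compress = if (cfg$norm == "batch") new_bn(cfg$c_mid),
    branch1 = branch_kernels(),
    branch2 = branch_kernels(),
    sca = if (cfg$attention_enabled)
      sca_init(cfg$c_cat, cfg$spatial_kernel, cfg$gamma, cfg$b),
    pw_fuse = lapply(seq_len(g), function(i)
      matrix(rnorm((cfg$out_channels %/% g) * (cfg$c_cat %/% g),
                   sd = sqrt(2 / (cfg$c_cat %/% g))),
             cfg$out_channels %/% g, cfg$c_cat %/% g))
  )
  state <- list(
    bn_compress = if (cfg$norm == "batch") new_bn_state(cfg$c_mid),
    branch1 = if (cfg$norm == "batch")
      lapply(seq_len(cfg$n_dw), function(i) new_bn_state(cfg$c_branch)),
    branch2 = if (cfg$norm == "batch")
      lapply(seq_len(cfg$n_dw), function(i) new_bn_state(cfg$c_branch))
  )
  structure(list(config = cfg, params = params, state = state),
            class = "ecdf_block")
}

#' Run one ECDF block
#'
#' @param x a `C_in x H x W` feature map.
#' @param block an [ecdf_block()].
#' @return A `C_out x H x W` feature map.
#' @export
ecdf_forward <- function(x, block) {
  check_feature_map(x)
  cfg <- block$config
  if (dim(x)[1] != cfg$in_channels) {
    stop("block expects ", cfg$in_channels, " input channels but the map has ",
         dim(x)[1], call. = FALSE)
  }
  r <- ecdf_fwd_batch(block$params, block$state, cfg, as_batch(x),
                      training = FALSE, want_cache = FALSE)
  drop_batch(r$y)
}

# closed-form trainable scalar count of one block
#' Closed-form parameter count of one ECDF block
#'
#' Sums the compression pointwise (`C_in * C_out / N`), the depthwise
#' cascades (`(N-2) * K^2 * C_out / (2N)`), the attention unit
#' (`2 k_s^2 + k_eca + 2` when enabled), the final pointwise
#' (`C_out^2 / (2 * groups)`), and normalization scales/shifts when batch
#' normalization is on. Always equals [count_parameters()] of a constructed
#' block.
#'
#' @param cfg an [ecdf_config()].
#' @return Integer scalar count.
#' @export
ecdf_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "ecdf_config"))
  K <- cfg$dw_kernel
  total <- cfg$in_channels * cfg$c_mid +
    (cfg$n - 2L) * K^2 * cfg$c_branch +
    cfg$c_cat * (cfg$out_channels %/% cfg$fusion_groups)
  if (cfg$attention_enabled) {
    total <- total + 2L * cfg$spatial_kernel^2 +
      eca_kernel_size(cfg$c_cat, cfg$gamma, cfg$b) + 2L
  }
  if (cfg$norm == "batch") {
    total <- total + 2L * cfg$c_mid + (cfg$n - 2L) * 2L * cfg$c_branch
  }
  as.numeric(total)
}

# ---- batched forward/backward ----

ecdf_fwd_batch <- function(params, state, cfg, x, training = FALSE,
                           want_cache = FALSE) {
  # compression pointwise (+ BN + relu)
  xc <- pw_fwd(x, params$pw_compress)
  bnc <- NULL
  if (cfg$norm == "batch") {
    bnc <- bn_fwd(xc, params$bn_compress$gamma, params$bn_compress$beta,
                  state$bn_compress$mean, state$bn_compress$var, training)
    state$bn_compress$mean <- bnc$rmean; state$bn_compress$var <- bnc$rvar
    xa <- relu_fwd(bnc$y)
  } else {
    xa <- xc
  }
  cb <- cfg$c_branch
  d <- dim(x)
  # concat layout: [compressed, branch1 stages..., branch2 stages...];
  # every cascade input/output is a slice of u, so u doubles as the cache
  u <- array(0, c(cfg$c_cat, d[2], d[3], d[4]))
  u[seq_len(cfg$c_mid), , , ] <- xa
  br_caches <- list(vector("list", cfg$n_dw), vector("list", cfg$n_dw))
  for (br in 1:2) {
    z <- xa[(br - 1L) * cb + seq_len(cb), , , , drop = FALSE]
    br_params <- if (br == 1L) params$branch1 else params$branch2
    br_state <- if (br == 1L) state$branch1 else state$branch2
    offset <- cfg$c_mid + (br - 1L) * cfg$n_dw * cb
    for (i in seq_len(cfg$n_dw)) {
      zi <- dw_fwd(z, br_params[[i]]$ker)
      if (cfg$norm == "batch") {
        bn <- bn_fwd(zi, br_params[[i]]$bn$gamma, br_params[[i]]$bn$beta,
                     br_state[[i]]$mean, br_state[[i]]$var, training)
        br_state[[i]]$mean <- bn$rmean; br_state[[i]]$var <- bn$rvar
        z <- relu_fwd(bn$y)
        br_caches[[br]][[i]] <- list(zi = zi, mu = bn$mu, invstd = bn$invstd)
      } else {
        z <- zi
        br_caches[[br]][[i]] <- list()
      }
      u[offset + (i - 1L) * cb + seq_len(cb), , , ] <- z
    }
    if (br == 1L) state$branch1 <- br_state else state$branch2 <- br_state
  }
  b1 <- list(caches = br_caches[[1]])
  b2 <- list(caches = br_caches[[2]])
  # attention gate
  if (cfg$attention_enabled) {
    sca <- sca_fwd(u, params$sca, want_cache = want_cache)
    ug <- sca$y
  } else {
    sca <- NULL
    ug <- u
  }
  # grouped fusion pointwise
  g <- cfg$fusion_groups
  ci <- cfg$c_cat %/% g
  co <- cfg$out_channels %/% g
  y <- array(0, c(cfg$out_channels, d[2], d[3], d[4]))
  for (k in seq_len(g)) {
    y[(k - 1L) * co + seq_len(co), , , ] <-
      pw_fwd(ug[(k - 1L) * ci + seq_len(ci), , , , drop = FALSE],
             params$pw_fuse[[k]])
  }
  cache <- NULL
  if (want_cache) {
    cache <- list(x = x, xc = xc,
                  bnc = if (!is.null(bnc)) bnc[c("mu", "invstd")],
                  b1 = b1$caches, b2 = b2$caches, u = u, sca = sca, ug = ug)
  }
  list(y = y, state = state, cache = cache)
}

ecdf_bwd_batch <- function(params, cfg, cache, dy) {
  g <- cfg$fusion_groups
  ci <- cfg$c_cat %/% g
  co <- cfg$out_channels %/% g
  dug <- array(0, dim(cache$ug))
  d_fuse <- vector("list", g)
  for (k in seq_len(g)) {
    r <- pw_bwd(cache$ug[(k - 1L) * ci + seq_len(ci), , , , drop = FALSE],
                params$pw_fuse[[k]],
                dy[(k - 1L) * co + seq_len(co), , , , drop = FALSE])
    dug[(k - 1L) * ci + seq_len(ci), , , ] <- r$dx
    d_fuse[[k]] <- r$dw
  }
  if (cfg$attention_enabled) {
    sr <- sca_bwd(cache$sca, params$sca, dug)
    du <- sr$dx
    d_sca <- sr$grads
  } else {
    du <- dug
    d_sca <- NULL
  }
  cb <- cfg$c_branch
  u <- cache$u
  # gradient w.r.t. the compressed activation (first c_mid concat channels)
  dxa <- du[seq_len(cfg$c_mid), , , , drop = FALSE]
  # a cascade stage's input is the previous concat slice (or the half of xa)
  stage_in <- function(offset, half_first, i) {
    if (i == 1L) {
      u[half_first + seq_len(cb), , , , drop = FALSE]
    } else {
      u[offset + (i - 2L) * cb + seq_len(cb), , , , drop = FALSE]
    }
  }
  back_branch <- function(br_params, br_caches, offset, half_first) {
    grads <- vector("list", cfg$n_dw)
    dz_next <- NULL   # gradient flowing into stage i's output from stage i+1
    for (i in rev(seq_len(cfg$n_dw))) {
      dz <- du[offset + (i - 1L) * cb + seq_len(cb), , , , drop = FALSE]
      if (!is.null(dz_next)) dz <- dz + dz_next
      cc <- br_caches[[i]]
      if (cfg$norm == "batch") {
        post <- u[offset + (i - 1L) * cb + seq_len(cb), , , , drop = FALSE]
        dz <- relu_bwd(post, dz)
        bb <- bn_bwd(cc$zi, cc$mu, cc$invstd, br_params[[i]]$bn$gamma, dz)
        grads[[i]] <- list(bn = list(gamma = bb$dgamma, beta = bb$dbeta))
        dz <- bb$dx
      } else {
        grads[[i]] <- list()
      }
      dd <- dw_bwd(stage_in(offset, half_first, i), br_params[[i]]$ker, dz)
      grads[[i]]$ker <- dd$dker
      dz_next <- dd$dx
    }
    list(grads = grads, dhalf = dz_next)
  }
  rb1 <- back_branch(params$branch1, cache$b1, cfg$c_mid, 0L)
  rb2 <- back_branch(params$branch2, cache$b2, cfg$c_mid + cfg$n_dw * cb, cb)
  if (cfg$n_dw > 0L) {
    dxa[seq_len(cb), , , ] <- dxa[seq_len(cb), , , , drop = FALSE] + rb1$dhalf
    dxa[cb + seq_len(cb), , , ] <-
      dxa[cb + seq_len(cb), , , , drop = FALSE] + rb2$dhalf
  }
  if (cfg$norm == "batch") {
    post_c <- u[seq_len(cfg$c_mid), , , , drop = FALSE]
    dxa <- relu_bwd(post_c, dxa)
    bb <- bn_bwd(cache$xc, cache$bnc$mu, cache$bnc$invstd,
                 params$bn_compress$gamma, dxa)
    d_bnc <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dxc <- bb$dx
  } else {
    d_bnc <- NULL
    dxc <- dxa
  }
  rc <- pw_bwd(cache$x, params$pw_compress, dxc)
  list(dx = rc$dx,
       grads = list(pw_compress = rc$dw, bn_compress = d_bnc,
                    branch1 = rb1$grads, branch2 = rb2$grads,
                    sca = d_sca, pw_fuse = d_fuse))
}
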