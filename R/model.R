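#' Network configuration
#'
#' The four-stage encoder/decoder plan: each encoder stage is an ECDF block
#' followed by 2 x 2 downsampling; each decoder stage is bicubic 2x
#' upsampling, channel concatenation with the matching encoder output
#' (order `[upsampled, skip]`), and an ECDF block; a final pointwise layer
#' maps 64 channels to the class scores. With the default channel plan
#' (64, 128, 256, 512) the decoder blocks therefore see 1024, 768, 384 and
#' 192 input channels. Inputs must have both spatial extents divisible by 16.
#'
#' @param stage_channels strictly increasing encoder stage widths.
#' @param num_classes output classes (2: background, lesion).
#' @param n compression factor shared by every block.
#' @param pooling `"max"` or `"average"` downsampling.
#' @param attention_enabled spatial-channel attention switch (ablation knob).
#' @param fusion_groups,norm,dw_kernel,spatial_kernel,gamma,b forwarded to
#'   [ecdf_config()].
#' @return A `network_config` object.
#' @export
network_config <- function(stage_channels = c(64L, 128L, 256L, 512L),
                           num_classes = 2L, n = 8L,
                           pooling = c("max", "average"),
                           attention_enabled = TRUE, fusion_groups = 2L,
                           norm = "batch", dw_kernel = 3L,
                           spatial_kernel = 7L, gamma = 2, b = 1) {
  pooling <- match.arg(pooling)
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != 4L || any(diff(stage_channels) <= 0L)) {
    stop("stage_channels must be four strictly increasing counts", call. = FALSE)
  }
  structure(list(stage_channels = stage_channels,
                 num_classes = as.integer(num_classes), n = as.integer(n),
                 pooling = pooling, attention_enabled = isTRUE(attention_enabled),
                 fusion_groups = as.integer(fusion_groups), norm = norm,
                 dw_kernel = as.integer(dw_kernel),
                 spatial_kernel = as.integer(spatial_kernel),
                 gamma = gamma, b = b),
            class = "network_config")
}

# the per-block (in, out) channel plan implied by a config
network_plan <- function(cfg) {
  s <- cfg$stage_channels
  list(
    enc = list(c(3L, s[1]), c(s[1], s[2]), c(s[2], s[3]), c(s[3], s[4])),
    dec = list(c(2L * s[4], s[4]),        # upsampled s4 + skip s4
               c(s[4] + s[3], s[3]),
               c(s[3] + s[2], s[2]),
               c(s[2] + s[1], s[1]))
  )
}

#' Build the segmentation network
#'
#' Instantiates every ECDF block of the encoder/decoder plan plus the final
#' pointwise classifier head, with seeded weight initialization.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight initialization stream.
#' @return An object of class `lmsaunet`.
#' @examples
#' net <- build_network(network_config(), seed = 1)
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  plan <- network_plan(cfg)
  mk <- function(io, stage) {
    tryCatch({
      bc <- ecdf_config(io[1], io[2], n = cfg$n, dw_kernel = cfg$dw_kernel,
                        attention_enabled = cfg$attention_enabled,
                        fusion_groups = cfg$fusion_groups, norm = cfg$norm,
                        spatial_kernel = cfg$spatial_kernel,
                        gamma = cfg$gamma, b = cfg$b)
      ecdf_block(bc)
    }, error = function(e)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  }
  set.seed(as.integer(seed))
  blocks <- c(
    lapply(seq_len(4L), function(i) mk(plan$enc[[i]], paste0("encoder ", i))),
    lapply(seq_len(4L), function(i) mk(plan$dec[[i]], paste0("decoder ", i)))
  )
  head_w <- matrix(rnorm(cfg$num_classes * cfg$stage_channels[1],
                         sd = sqrt(1 / cfg$stage_channels[1])),
                   cfg$num_classes, cfg$stage_channels[1])
  structure(list(config = cfg, seed = as.integer(seed),
                 params = list(blocks = lapply(blocks, `[[`, "params"),
                               head = head_w),
                 state = list(blocks = lapply(blocks, `[[`, "state")),
                 block_configs = lapply(blocks, `[[`, "config")),
            class = "lmsaunet")
}

check_input_size <- function(h, w) {
  if (h %% 16L != 0L || w %% 16L != 0L) {
    stop("input spatial size ", h, " x ", w,
         " must be divisible by 16 (four 2x downsampling stages)",
         call. = FALSE)
  }
}

# full batched forward; returns logits and, when training, the tape needed
# for the backward sweep
net_fwd <- function(net, x, training = FALSE, want_cache = FALSE,
                    trace = FALSE) {
  d <- dim(x)
  if (d[1] != 3L) stop("network input must have 3 channels", call. = FALSE)
  check_input_size(d[2], d[3])
  P <- net$params; S <- net$state; BC <- net$block_configs
  skips <- vector("list", 4L)
  pools <- vector("list", 4L)
  caches <- vector("list", 8L)
  shapes <- list()
  note <- function(name, z) {
    if (trace) shapes[[length(shapes) + 1L]] <<- c(list(block = name),
                                                   as.list(dim(z)[1:3]))
  }
  z <- x
  for (i in 1:4) {
    r <- ecdf_fwd_batch(P$blocks[[i]], S$blocks[[i]], BC[[i]], z,
                        training, want_cache)
    S$blocks[[i]] <- r$state
    caches[[i]] <- r$cache
    skips[[i]] <- r$y
    note(paste0("ECDF BLOCK ", i), r$y)
    pr <- pool_fwd(r$y, net$config$pooling)
    pools[[i]] <- pr
    z <- pr$y
    note(paste0("DOWNSAMPLING ", i), z)
  }
  ups <- vector("list", 4L)
  for (i in 1:4) {
    hin <- dim(z)[2]; win <- dim(z)[3]
    ups[[i]] <- c(hin, win)
    z <- upsample_fwd(z)
    note(paste0("UPSAMPLING ", i), z)
    skip <- skips[[5L - i]]
    cat_in <- array(0, c(dim(z)[1] + dim(skip)[1], dim(z)[2:4]))
    cat_in[seq_len(dim(z)[1]), , , ] <- z
    cat_in[dim(z)[1] + seq_len(dim(skip)[1]), , , ] <- skip
    r <- ecdf_fwd_batch(P$blocks[[4L + i]], S$blocks[[4L + i]], BC[[4L + i]],
                        cat_in, training, want_cache)
    S$blocks[[4L + i]] <- r$state
    caches[[4L + i]] <- r$cache
    if (want_cache) caches[[4L + i]]$up_ch <- dim(z)[1]
    z <- r$y
    note(paste0("ECDF BLOCK ", 4L + i), z)
  }
  logits <- pw_fwd(z, P$head)
  note("PWCONV", logits)
  out <- list(logits = logits, state = S)
  if (want_cache) {
    out$cache <- list(blocks = caches, pools = pools, ups = ups,
                      head_in = z)
  }
  if (trace) out$shapes <- dplyr::bind_rows(lapply(shapes, function(s)
    tibble::tibble(block = s$block, channels = s[[2]],
                   height = s[[3]], width = s[[4]])))
  out
}

# backward sweep; returns gradients in the same nesting as net$params
net_bwd <- function(net, cache, dlogits) {
  P <- net$params; BC <- net$block_configs
  hr <- pw_bwd(cache$head_in, P$head, dlogits)
  d_head <- hr$dw
  dz <- hr$dx
  gblocks <- vector("list", 8L)
  dskip <- vector("list", 4L)
  for (i in 4:1) {
    r <- ecdf_bwd_batch(P$blocks[[4L + i]], BC[[4L + i]],
                        cache$blocks[[4L + i]], dz)
    gblocks[[4L + i]] <- r$grads
    upc <- cache$blocks[[4L + i]]$up_ch
    dup <- r$dx[seq_len(upc), , , , drop = FALSE]
    dskip[[5L - i]] <- r$dx[upc + seq_len(dim(r$dx)[1] - upc), , , ,
                            drop = FALSE]
    dz <- upsample_bwd(dup, cache$ups[[i]][1], cache$ups[[i]][2])
  }
  for (i in 4:1) {
    dpool <- pool_bwd(cache$pools[[i]], dz)
    dy <- dpool + dskip[[i]]
    r <- ecdf_bwd_batch(P$blocks[[i]], BC[[i]], cache$blocks[[i]], dy)
    gblocks[[i]] <- r$grads
    dz <- r$dx
  }
  list(grads = list(blocks = gblocks, head = d_head), dx = dz)
}

#' Forward pass
#'
#' @param object a built network.
#' @param ... passed to methods.
#' @export
forward <- function(object, ...) UseMethod("forward")

#' @rdname forward
#' @param x a `3 x H x W` image (values in any real range; training uses
#'   `[0, 1]`) with H and W divisible by 16.
#' @return A `num_classes x H x W` array of class scores (logits).
#' @export
forward.lmsaunet <- function(object, x, ...) {
  check_feature_map(x)
  drop_batch(net_fwd(object, as_batch(x), training = FALSE)$logits)
}

#' @rdname forward
#' @param type `"logits"`, `"prob"` (foreground probability map) or `"mask"`.
#' @export
predict.lmsaunet <- function(object, x, type = c("mask", "prob", "logits"),
                             ...) {
  type <- match.arg(type)
  logits <- forward(object, x)
  switch(type,
         logits = logits,
         prob = foreground_probability(logits),
         mask = predict_mask(logits))
}

#' Hard segmentation mask from class scores
#'
#' The foreground probability is the two-class normalized exponential of the
#' scores; pixels with probability strictly above 0.5 become lesion (1), ties
#' go to background.
#'
#' @param logits a `2 x H x W` score array.
#' @return An `H x W` binary matrix.
#' @export
predict_mask <- function(logits) {
  (foreground_probability(logits) > 0.5) * 1
}

#' Summarize the network
#'
#' Produces the per-block shape table (output size, input channels, output
#' channels, one row per block for a given input size) together with the
#' parameter report.
#'
#' @param object an `lmsaunet` network.
#' @param input_size square input side in pixels (divisible by 16).
#' @param ... unused.
#' @return A list of class `lmsaunet_summary` with elements `shapes` (tibble)
#'   and `params` (the [count_parameters()] report).
#' @export
summary.lmsaunet <- function(object, input_size = 256L, ...) {
  check_input_size(input_size, input_size)
  cfg <- object$config
  plan <- network_plan(cfg)
  s <- as.integer(input_size)
  rows <- list()
  add <- function(block, size, cin, cout) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      block = block, output_size = paste0(size, " x ", size),
      in_channels = as.integer(cin), out_channels = as.integer(cout))
  }
  sz <- s
  for (i in 1:4) {
    add(paste0("ECDF BLOCK ", i), sz, plan$enc[[i]][1], plan$enc[[i]][2])
    sz <- sz %/% 2L
    add(paste0("DOWNSAMPLING ", i), sz, plan$enc[[i]][2], plan$enc[[i]][2])
  }
  for (i in 1:4) {
    sz <- sz * 2L
    up_ch <- if (i == 1L) cfg$stage_channels[4] else plan$dec[[i - 1L]][2]
    add(paste0("UPSAMPLING ", i), sz, up_ch, up_ch)
    add(paste0("ECDF BLOCK ", 4L + i), sz, plan$dec[[i]][1], plan$dec[[i]][2])
  }
  add("PWCONV", sz, cfg$stage_channels[1], cfg$num_classes)
  structure(list(shapes = dplyr::bind_rows(rows),
                 params = count_parameters(object),
                 input_size = s),
            class = "lmsaunet_summary")
}

#' @export
print.lmsaunet_summary <- function(x, ...) {
  cat("Layer plan at", x$input_size, "x", x$input_size, "input:\n")
  print(as.data.frame(x$shapes), row.names = FALSE)
  cat("\nTrainable parameters:", attr(x$params, "total"),
      sprintf("(%.4f M)\n", attr(x$params, "total_millions")))
  invisible(x)
}

#' @export
print.lmsaunet <- function(x, ...) {
  p <- count_parameters(x)
  cat("<lmsaunet> N =", x$config$n,
      "| attention:", x$config$attention_enabled,
      "| pooling:", x$config$pooling,
      "| params:", sprintf("%.4f M\n", attr(p, "total_millions")))
  invisible(x)
}
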