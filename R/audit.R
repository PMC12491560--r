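#' Count trainable parameters
#'
#' Walks a model (a full network, a single ECDF block, a [conv_params()]
#' layer, or any nested list of those) and tallies every trainable scalar.
#' Normalization scales/shifts and attention scalars are reported as their
#' own components so either inclusion convention can be read off the table.
#'
#' @param model the object to audit.
#' @param ... unused.
#' @return A tibble of class `lmsa_param_report` with columns `component`,
#'   `kind` (`conv`, `norm`, `attention`) and `params`, plus attributes
#'   `total` and `total_millions`.
#' @examples
#' count_parameters(conv_params(64, 128, 1, weights = numeric(8192)))
#' @export
count_parameters <- function(model, ...) UseMethod("count_parameters")

param_report <- function(rows, mac_count = NA_real_) {
  tb <- dplyr::bind_rows(rows)
  structure(tb, class = c("lmsa_param_report", class(tb)),
            total = sum(tb$params),
            total_millions = sum(tb$params) / 1e6,
            mac_count = mac_count,
            flop_count = if (is.na(mac_count)) NA_real_ else 2 * mac_count)
}

prow <- function(component, kind, params) {
  tibble::tibble(component = component, kind = kind, params = as.numeric(params))
}

#' @export
count_parameters.conv_params <- function(model, ...) {
  param_report(list(prow(
    if (model$depthwise) "depthwise_conv" else "conv", "conv",
    length(model$weights))))
}

block_param_rows <- function(p, cfg, label) {
  rows <- list(prow(paste0(label, ".pw_compress"), "conv",
                    length(p$pw_compress)))
  if (!is.null(p$bn_compress)) {
    rows <- c(rows, list(prow(paste0(label, ".norm"), "norm",
                              2L * cfg$c_mid + cfg$n_dw * 2L * 2L * cfg$c_branch)))
  }
  if (cfg$n_dw > 0L) {
    rows <- c(rows, list(prow(paste0(label, ".depthwise"), "conv",
                              2L * cfg$n_dw * cfg$c_branch * cfg$dw_kernel^2)))
  }
  if (!is.null(p$sca)) {
    rows <- c(rows, list(prow(paste0(label, ".attention"), "attention",
                              length(p$sca$w_sp) + length(p$sca$w_ch) + 2L)))
  }
  c(rows, list(prow(paste0(label, ".pw_fuse"), "conv",
                    sum(vapply(p$pw_fuse, length, numeric(1))))))
}

#' @export
count_parameters.ecdf_block <- function(model, ...) {
  param_report(block_param_rows(model$params, model$config, "ecdf"))
}

#' @export
count_parameters.lmsaunet <- function(model, ...) {
  labels <- c(paste0("enc", 1:4), paste0("dec", 1:4))
  rows <- list()
  for (i in 1:8) {
    rows <- c(rows, block_param_rows(model$params$blocks[[i]],
                                     model$block_configs[[i]], labels[i]))
  }
  rows <- c(rows, list(prow("head", "conv", length(model$params$head))))
  param_report(rows)
}

#' @export
count_parameters.default <- function(model, ...) {
  count_leaves <- function(x) {
    if (is.numeric(x)) return(length(x))
    if (inherits(x, "conv_params")) return(length(x$weights))
    if (is.list(x)) return(sum(vapply(x, count_leaves, numeric(1))))
    0
  }
  if (is.list(model) && length(model) > 0 && !is.null(names(model))) {
    rows <- lapply(names(model), function(nm)
      prow(nm, "conv", count_leaves(model[[nm]])))
  } else {
    rows <- list(prow("model", "conv", count_leaves(model)))
  }
  param_report(rows)
}

#' @export
print.lmsa_param_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("# total: %s scalars (%.4f M)\n",
              format(attr(x, "total"), big.mark = ","),
              attr(x, "total_millions")))
  if (!is.na(attr(x, "mac_count"))) {
    cat(sprintf("# MACs: %s (FLOPs: %s)\n",
                format(attr(x, "mac_count"), big.mark = ","),
                format(attr(x, "flop_count"), big.mark = ",")))
  }
  invisible(x)
}

#' @rdname tidy.lmsaunet_fit
#' @export
glance.lmsa_param_report <- function(x, ...) {
  tibble::tibble(total = attr(x, "total"),
                 total_millions = attr(x, "total_millions"),
                 mac_count = attr(x, "mac_count"),
                 flop_count = attr(x, "flop_count"))
}

# ---- multiply-accumulate estimation ----

# MAC cost of one ECDF block at spatial extent H x W. Conventions (documented
# in the methods vignette): convolution MACs = weight_count * H * W;
# attention counts its pooling accumulations, 1-d conv, spatial conv and the
# two gate operations; normalization and activations are excluded.
ecdf_macs <- function(cfg, h, w) {
  hw <- as.numeric(h) * w
  macs <- cfg$in_channels * cfg$c_mid * hw +
    (cfg$n - 2) * cfg$dw_kernel^2 * cfg$c_branch * hw +
    cfg$c_cat * cfg$out_channels * hw / cfg$fusion_groups
  if (cfg$attention_enabled) {
    k <- eca_kernel_size(cfg$c_cat, cfg$gamma, cfg$b)
    macs <- macs + cfg$c_cat * hw +                 # global average pool
      k * cfg$c_cat +                               # 1-d channel conv
      2 * cfg$spatial_kernel^2 * hw +               # 2 -> 1 spatial conv
      2 * cfg$c_cat * hw                            # gate build + apply
  }
  macs
}

#' Estimate multiply-accumulate operations
#'
#' Counts MACs for a forward pass at the stated input size: each convolution
#' contributes `weight_count * output_H * output_W`, bicubic upsampling its
#' 4-tap separable arithmetic, average pooling its window sums, and attention
#' its pooling/convolution/gating arithmetic. `flop_count = 2 * mac_count` by
#' the usual 1-MAC-is-2-FLOPs convention; both are attached to the report.
#'
#' @param model an `lmsaunet` network, a [conv_params()] layer, or a list of
#'   layers (an empty list costs 0).
#' @param input_height,input_width spatial extent of the input (divisible by
#'   16 for the full network).
#' @return A `lmsa_param_report` with `mac_count`/`flop_count` attributes.
#' @export
estimate_macs <- function(model, input_height, input_width) {
  UseMethod("estimate_macs")
}

#' @export
estimate_macs.conv_params <- function(model, input_height, input_width) {
  r <- count_parameters(model)
  m <- length(model$weights) * as.numeric(input_height) * input_width
  attr(r, "mac_count") <- m
  attr(r, "flop_count") <- 2 * m
  r
}

#' @export
estimate_macs.default <- function(model, input_height, input_width) {
  if (is.list(model)) {
    m <- sum(vapply(model, function(l)
      attr(estimate_macs(l, input_height, input_width), "mac_count"),
      numeric(1)))
    r <- count_parameters(model)
    attr(r, "mac_count") <- if (length(model)) m else 0
    attr(r, "flop_count") <- 2 * attr(r, "mac_count")
    return(r)
  }
  stop("cannot estimate MACs for this object", call. = FALSE)
}

#' @export
estimate_macs.lmsaunet <- function(model, input_height, input_width) {
  if (input_height %% 16L != 0L || input_width %% 16L != 0L) {
    stop("MAC estimation needs a spatial size divisible by 16; got ",
         input_height, " x ", input_width, call. = FALSE)
  }
  cfg <- model$config
  h <- as.numeric(input_height); w <- as.numeric(input_width)
  macs <- 0
  for (i in 1:4) {
    macs <- macs + ecdf_macs(model$block_configs[[i]], h, w)
    h <- h / 2; w <- w / 2
    if (cfg$pooling == "average") {
      macs <- macs + 4 * cfg$stage_channels[i] * h * w
    }
  }
  for (i in 1:4) {
    cin <- model$block_configs[[4L + i]]$in_channels
    up_ch <- cin - model$config$stage_channels[5L - i]
    macs <- macs + 24 * up_ch * h * w                # separable 4-tap bicubic
    h <- h * 2; w <- w * 2
    macs <- macs + ecdf_macs(model$block_configs[[4L + i]], h, w)
  }
  macs <- macs + length(model$params$head) * h * w
  r <- count_parameters(model)
  attr(r, "mac_count") <- macs
  attr(r, "flop_count") <- 2 * macs
  r
}
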