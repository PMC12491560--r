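#' Loss configuration
#'
#' The training objective is `alpha * BCE + beta * soft-IoU` with the
#' weights 0.25 and 0.75 (the combination found to give the best overlap
#' scores). `epsilon` guards the soft-IoU divisor; `delta` clamps predicted
#' probabilities inside the logs of the cross-entropy term.
#'
#' @param alpha_loss weight on binary cross-entropy (default 0.25).
#' @param beta_loss weight on the soft-IoU loss (default 0.75).
#' @param epsilon divisor guard (default 1e-6).
#' @param delta probability clamp for log stability (default 1e-7).
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha_loss = 0.25, beta_loss = 0.75, epsilon = 1e-6,
                        delta = 1e-7) {
  stopifnot(alpha_loss >= 0, beta_loss >= 0, epsilon > 0, delta > 0)
  structure(list(alpha_loss = alpha_loss, beta_loss = beta_loss,
                 epsilon = epsilon, delta = delta), class = "loss_config")
}

#' Foreground probability from two-class scores
#'
#' `sigma(logit_fg - logit_bg)`, which is algebraically identical to the
#' foreground entry of the two-class normalized exponential; this bridges the
#' two-channel classifier head to the single-probability loss.
#'
#' @param logits a `2 x H x W` score array (channel 1 background, channel 2
#'   foreground).
#' @return An `H x W` probability matrix strictly inside (0, 1).
#' @export
foreground_probability <- function(logits) {
  d <- dim(logits)
  if (is.null(d) || d[1] != 2L) {
    stop("foreground probability needs a 2-channel score map", call. = FALSE)
  }
  if (length(d) == 3L) {
    plogis(logits[2, , ] - logits[1, , ])
  } else {
    plogis(logits[2, , , ] - logits[1, , , ])
  }
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary cross-entropy loss
#'
#' Mean over all pixels of `-(y log yhat + (1-y) log(1-yhat))`, with `yhat`
#' clamped to `[delta, 1-delta]`.
#'
#' @param y_hat predicted probability map.
#' @param y binary reference map.
#' @param delta clamp inside the logarithms.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y_hat, y, delta = 1e-7) {
  check_same_shape(y_hat, y)
  p <- pmin(pmax(y_hat, delta), 1 - delta)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft-IoU loss
#'
#' `1 - sum(yhat * y) / (sum(yhat + y - yhat * y) + epsilon)`, summing over
#' all pixels; a differentiable relaxation of one minus the overlap ratio.
#'
#' @inheritParams bce_loss
#' @param eps divisor guard.
#' @return Scalar in `[0, 1]`.
#' @export
iou_loss <- function(y_hat, y, eps = 1e-6) {
  check_same_shape(y_hat, y)
  inter <- sum(y_hat * y)
  union <- sum(y_hat + y - y_hat * y)
  1 - inter / (union + eps)
}

#' Joint segmentation loss
#'
#' @inheritParams bce_loss
#' @param cfg a [loss_config()].
#' @return `alpha_loss * bce + beta_loss * iou`.
#' @export
total_loss <- function(y_hat, y, cfg = loss_config()) {
  cfg$alpha_loss * bce_loss(y_hat, y, cfg$delta) +
    cfg$beta_loss * iou_loss(y_hat, y, cfg$epsilon)
}

# batched loss and its gradient w.r.t. the two-channel logits.
# logits (2,H,W,B), y (H,W,B); per-image losses averaged over the batch.
loss_fwd_bwd <- function(logits, y, cfg = loss_config()) {
  d <- dim(logits)
  H <- d[2]; W <- d[3]; B <- d[4]
  z <- logits[2, , , , drop = TRUE] - logits[1, , , , drop = TRUE]
  dim(z) <- c(H, W, B)
  p <- plogis(z)
  pc <- pmin(pmax(p, cfg$delta), 1 - cfg$delta)
  hw <- H * W
  pm <- matrix(pc, hw); ym <- matrix(y, hw)
  bce_b <- -colMeans(ym * log(pm) + (1 - ym) * log(1 - pm))
  inter <- colSums(pm * ym)
  union <- colSums(pm + ym - pm * ym)
  iou_b <- 1 - inter / (union + cfg$epsilon)
  loss <- mean(cfg$alpha_loss * bce_b + cfg$beta_loss * iou_b)
  # d loss / d p (clamped region has zero slope only at the clamp bounds;
  # the clamp is inactive away from 0/1 so we use the unclamped gradient)
  dbce <- (pm - ym) / (pm * (1 - pm)) / hw
  ue <- union + cfg$epsilon
  diou <- -sweep(sweep(matrix(ym, hw), 2, ue, "*") -
                   (1 - ym) * rep(inter, each = hw), 2, ue^2, "/")
  dp <- (cfg$alpha_loss * dbce + cfg$beta_loss * diou) / B
  dz <- dp * pm * (1 - pm)
  dlogits <- array(0, d)
  dlogits[2, , , ] <- dz
  dlogits[1, , , ] <- -dz
  list(loss = loss, dlogits = dlogits, prob = p,
       bce = mean(bce_b), iou = mean(iou_b))
}

#' Pixel confusion counts
#'
#' @param pred,truth binary maps of identical shape with values in `{0, 1}`.
#' @return A `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  check_same_shape(pred, truth)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("confusion counts need strictly binary maps", call. = FALSE)
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @rdname confusion
#' @param ... `confusion_counts` objects to pool (micro-aggregation).
#' @export
pool_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) &&
      !inherits(cs[[1]], "confusion_counts")) cs <- cs[[1]]
  structure(list(tp = sum(vapply(cs, `[[`, numeric(1), "tp")),
                 fp = sum(vapply(cs, `[[`, numeric(1), "fp")),
                 tn = sum(vapply(cs, `[[`, numeric(1), "tn")),
                 fn = sum(vapply(cs, `[[`, numeric(1), "fn"))),
            class = "confusion_counts")
}

check_counts <- function(c) {
  if (c$tp + c$fp + c$tn + c$fn == 0) {
    stop("confusion counts are all zero", call. = FALSE)
  }
}

#' Segmentation metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `iou = TP/(TP+FP+FN)`,
#' `dice = 2 TP/(2 TP+FP+FN)`. When a class is absent from both maps the
#' overlap ratios are defined as 1 (a perfect prediction of an empty class).
#'
#' @param c a [confusion()] result.
#' @return Scalar metric value.
#' @export
accuracy <- function(c) {
  check_counts(c)
  (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)
}

#' @rdname accuracy
#' @export
iou <- function(c) {
  check_counts(c)
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1)
  c$tp / den
}

#' @rdname accuracy
#' @export
dice <- function(c) {
  check_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Frequency-weighted IoU
#'
#' `sum_c (N_c / N_total) * IoU_c`: per-class overlap weighted by that
#' class's pixel frequency in the reference, robust to the heavy
#' background/lesion imbalance of dermoscopy masks. The background class's
#' IoU uses TN as its true-positive count.
#'
#' @param per_class_iou numeric vector of per-class IoU values.
#' @param freq numeric vector of per-class reference pixel counts (same
#'   order).
#' @return Scalar in `[0, 1]`.
#' @export
fwiou <- function(per_class_iou, freq) {
  if (length(per_class_iou) != length(freq)) {
    stop("need one frequency per class", call. = FALSE)
  }
  if (any(freq < 0) || sum(freq) <= 0) {
    stop("class frequencies must be non-negative with a positive total",
         call. = FALSE)
  }
  sum(freq / sum(freq) * per_class_iou)
}

#' Full metric report from confusion counts
#'
#' @param c a [confusion()] result.
#' @return A one-row tibble with `accuracy`, `iou_fg`, `iou_bg`, `miou`,
#'   `dice`, `fwiou`.
#' @export
seg_metrics <- function(c) {
  check_counts(c)
  bg <- structure(list(tp = c$tn, fp = c$fn, tn = c$tp, fn = c$fp),
                  class = "confusion_counts")
  iou_fg <- iou(c)
  iou_bg <- iou(bg)
  n_fg <- c$tp + c$fn
  n_bg <- c$tn + c$fp
  tibble::tibble(
    accuracy = accuracy(c),
    iou_fg = iou_fg,
    iou_bg = iou_bg,
    miou = (iou_fg + iou_bg) / 2,
    dice = dice(c),
    fwiou = fwiou(c(iou_bg, iou_fg), c(n_bg, n_fg)))
}
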