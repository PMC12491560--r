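# Brute-force reference implementations used as independent oracles, plus
# small shared fixtures. These deliberately use nested loops / direct formula
# evaluation, never the package's own computational path.

rand_fm <- function(channels, height, width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feature_map(rnorm(channels * height * width), channels, height, width)
}

# per-pixel matrix-vector product
oracle_pointwise <- function(x, w) {
  d <- dim(x)
  out <- array(0, c(nrow(w), d[2], d[3]))
  for (h in seq_len(d[2])) for (v in seq_len(d[3])) {
    out[, h, v] <- as.numeric(w %*% x[, h, v])
  }
  out
}

# per-channel 2-d correlation with zero padding
oracle_depthwise <- function(x, ker) {
  d <- dim(x); K <- dim(ker)[2]; pad <- K %/% 2
  out <- array(0, d)
  for (c in seq_len(d[1])) {
    for (h in seq_len(d[2])) for (v in seq_len(d[3])) {
      s <- 0
      for (i in seq_len(K)) for (j in seq_len(K)) {
        hh <- h + i - 1 - pad; vv <- v + j - 1 - pad
        if (hh >= 1 && hh <= d[2] && vv >= 1 && vv <= d[3]) {
          s <- s + ker[c, i, j] * x[c, hh, vv]
        }
      }
      out[c, h, v] <- s
    }
  }
  out
}

# nested-loop 2x2 window pooling
oracle_pool <- function(x, mode) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] / 2, d[3] / 2))
  for (c in seq_len(d[1])) for (h in seq_len(d[2] / 2)) for (v in seq_len(d[3] / 2)) {
    win <- x[c, (2 * h - 1):(2 * h), (2 * v - 1):(2 * v)]
    out[c, h, v] <- if (mode == "max") max(win) else mean(win)
  }
  out
}

# direct per-pixel bicubic (Keys a = -1/2) at half-pixel-centered scale 2
# with clamped borders; independent of the package's separable pass
oracle_bicubic_x2 <- function(x) {
  keys <- function(t) {
    t <- abs(t); a <- -0.5
    if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
    else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
    else 0
  }
  d <- dim(x)
  out <- array(0, c(d[1], 2 * d[2], 2 * d[3]))
  for (c in seq_len(d[1])) {
    for (ho in 0:(2 * d[2] - 1)) for (vo in 0:(2 * d[3] - 1)) {
      uh <- ho / 2 - 0.25; uv <- vo / 2 - 0.25
      ih <- floor(uh); iv <- floor(uv)
      s <- 0
      for (p in -1:2) for (q in -1:2) {
        hh <- min(max(ih + p, 0), d[2] - 1)
        vv <- min(max(iv + q, 0), d[3] - 1)
        s <- s + keys(uh - (ih + p)) * keys(uv - (iv + q)) * x[c, hh + 1, vv + 1]
      }
      out[c, ho + 1, vo + 1] <- s
    }
  }
  out
}

# channel max/mean pooling oracle
oracle_channel_pool <- function(x) {
  d <- dim(x)
  out <- array(0, c(2, d[2], d[3]))
  for (h in seq_len(d[2])) for (v in seq_len(d[3])) {
    out[1, h, v] <- max(x[, h, v])
    out[2, h, v] <- mean(x[, h, v])
  }
  out
}

# zero-padded same-length 1-d correlation oracle
oracle_conv1d <- function(s, w) {
  k <- length(w); p <- k %/% 2; n <- length(s)
  sp <- c(rep(0, p), s, rep(0, p))
  vapply(seq_len(n), function(i) sum(w * sp[i:(i + k - 1)]), numeric(1))
}

# dense 2-d convolution (Cin -> Cout) oracle with zero padding
oracle_conv2 <- function(x, wt) {
  dw <- dim(wt)  # (Cout, Cin, K, K)
  d <- dim(x); K <- dw[3]; pad <- K %/% 2
  out <- array(0, c(dw[1], d[2], d[3]))
  for (o in seq_len(dw[1])) for (h in seq_len(d[2])) for (v in seq_len(d[3])) {
    s <- 0
    for (ci in seq_len(dw[2])) for (i in seq_len(K)) for (j in seq_len(K)) {
      hh <- h + i - 1 - pad; vv <- v + j - 1 - pad
      if (hh >= 1 && hh <= d[2] && vv >= 1 && vv <= d[3]) {
        s <- s + wt[o, ci, i, j] * x[ci, hh, vv]
      }
    }
    out[o, h, v] <- s
  }
  out
}

unclass_m <- function(m) { attributes(m) <- list(dim = dim(m)); m }

# tiny network configuration shared by training-mechanics tests
tiny_net_config <- function(...) {
  network_config(n = 2L, ...)
}
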