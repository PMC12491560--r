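test_that("foreground probability equals the two-class softmax", {
  lg <- feature_map(0, 2, 3, 3)
  expect_true(all(foreground_probability(lg) == 0.5))
  lg[2, , ] <- 30
  expect_true(all(foreground_probability(lg) > 1 - 1e-12))
  set.seed(70)
  lgr <- feature_map(rnorm(2 * 3 * 3), 2, 3, 3)
  soft <- exp(lgr[2, , ]) / (exp(lgr[1, , ]) + exp(lgr[2, , ]))
  expect_equal(foreground_probability(lgr), soft, tolerance = 1e-7)
})

test_that("binary cross-entropy matches its closed forms", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(bce_loss(matrix(0.5, 2, 2), y), log(2), tolerance = 1e-12)
  expect_lte(bce_loss(y, y), -log(1 - 1e-7) + 1e-12)
  yh <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2)
  expect_equal(bce_loss(yh, y),
               mean(-log(c(0.9, 0.9, 0.8, 0.8))), tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 3), y), "shape")
})

test_that("soft-IoU loss matches its closed forms", {
  ones <- matrix(1, 4, 4)
  expect_equal(iou_loss(ones, ones), 1 - 16 / (16 + 1e-6), tolerance = 1e-12)
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  b <- matrix(0, 4, 4); b[3:4, ] <- 1
  expect_equal(iou_loss(a, b), 1)
  # |truth| = 8, overlap 4, union 12
  tr <- matrix(0, 4, 4); tr[1:2, ] <- 1
  pr <- matrix(0, 4, 4); pr[2:3, ] <- 1
  expect_equal(iou_loss(pr, tr), 1 - 4 / (12 + 1e-6), tolerance = 1e-9)
})

test_that("the joint loss combines its terms with the 0.25/0.75 weights", {
  y <- matrix(1, 8, 8)
  yh <- matrix(0.5, 8, 8)
  p <- 64
  expected <- 0.25 * log(2) + 0.75 * (1 - 0.5 * p / (0.5 * p + p - 0.5 * p + 1e-6))
  expect_equal(total_loss(yh, y), expected, tolerance = 1e-9)
  expect_equal(total_loss(yh, y), 0.5483, tolerance = 1e-3)
  # degenerate weights reduce to pure cross-entropy
  expect_equal(total_loss(yh, y, loss_config(alpha_loss = 1, beta_loss = 0)),
               bce_loss(yh, y), tolerance = 1e-12)
  expect_lt(total_loss(y, y), 1e-5)
})

test_that("confusion counts partition the pixels", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  cc <- confusion(a, a)
  expect_equal(cc$fp + cc$fn, 0)
  cn <- confusion(1 - a, a)
  expect_equal(cn$tp + cn$tn, 0)
  tr <- matrix(0, 10, 10); tr[1:2, 1:5] <- 1          # 10 true pixels
  pr <- matrix(0, 10, 10); pr[1:2, 2:6] <- 1          # 10 predicted, 8 overlap
  cc2 <- confusion(pr, tr)
  expect_equal(unlist(cc2[c("tp", "fp", "fn", "tn")]),
               c(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 100)
  expect_error(confusion(a * 0.5, a), "binary")
})

test_that("accuracy, IoU and Dice follow their formulas and identities", {
  cc <- structure(list(tp = 8, fp = 2, tn = 88, fn = 2),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 0.96)
  expect_equal(iou(cc), 8 / 12)
  expect_equal(dice(cc), 0.8)
  # Dice = 2 IoU / (1 + IoU) for arbitrary counts
  set.seed(71)
  for (i in 1:10) {
    c2 <- structure(as.list(setNames(rpois(4, 20) + 1,
                                     c("tp", "fp", "tn", "fn"))),
                    class = "confusion_counts")
    expect_equal(dice(c2), 2 * iou(c2) / (1 + iou(c2)), tolerance = 1e-12)
    expect_lte(iou(c2), dice(c2))
    expect_gte(iou(c2), 0); expect_lte(dice(c2), 1)
  }
  perfect <- structure(list(tp = 5, fp = 0, tn = 95, fn = 0),
                       class = "confusion_counts")
  expect_equal(c(accuracy(perfect), iou(perfect), dice(perfect)), c(1, 1, 1))
})

test_that("frequency-weighted IoU weighs per-class overlap by class frequency", {
  expect_equal(fwiou(c(1, 1), c(30, 70)), 1)
  expect_equal(fwiou(c(8 / 12, 88 / 92), c(10, 90)),
               0.1 * 8 / 12 + 0.9 * 88 / 92)
  expect_equal(fwiou(c(8 / 12, 88 / 92), c(10, 90)), 0.9275, tolerance = 1e-3)
  # lies between the per-class extremes
  expect_gte(fwiou(c(0.4, 0.9), c(25, 75)), 0.4)
  expect_lte(fwiou(c(0.4, 0.9), c(25, 75)), 0.9)
  expect_error(fwiou(c(1, 1), c(1, 2, 3)), "per class")
})

test_that("the metric report is coherent and handles empty foreground", {
  cc <- confusion(matrix(0, 4, 4), matrix(0, 4, 4))
  m <- seg_metrics(cc)
  expect_equal(m$fwiou, 1)           # absent class counts as perfectly predicted
  expect_equal(m$iou_fg, 1)
  tr <- matrix(0, 10, 10); tr[1:2, 1:5] <- 1
  pr <- matrix(0, 10, 10); pr[1:2, 2:6] <- 1
  m2 <- seg_metrics(confusion(pr, tr))
  expect_equal(m2$miou, (m2$iou_fg + m2$iou_bg) / 2)
  expect_equal(m2$fwiou, 0.1 * m2$iou_fg + 0.9 * m2$iou_bg)
})

test_that("the batched loss gradient matches finite differences", {
  ns <- asNamespace("lmsaunet")
  set.seed(72)
  lg <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  y <- array((runif(3 * 3 * 2) > 0.5) * 1, c(3, 3, 2))
  r <- ns$loss_fwd_bwd(lg, y)
  eps <- 1e-6
  for (probe in list(c(1, 2, 2, 1), c(2, 1, 3, 2), c(2, 3, 1, 1))) {
    lp <- lg; lp[probe[1], probe[2], probe[3], probe[4]] <- lp[probe[1], probe[2], probe[3], probe[4]] + eps
    lm <- lg; lm[probe[1], probe[2], probe[3], probe[4]] <- lm[probe[1], probe[2], probe[3], probe[4]] - eps
    fd <- (ns$loss_fwd_bwd(lp, y)$loss - ns$loss_fwd_bwd(lm, y)$loss) / (2 * eps)
    expect_equal(r$dlogits[probe[1], probe[2], probe[3], probe[4]], fd,
                 tolerance = 1e-5)
  }
})
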