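test_that("mask generation is deterministic and star-convex around its center", {
  spec <- synthetic_spec(image_size = 48L, seed = 1L)
  m1 <- generate_mask(spec, 101)
  m2 <- generate_mask(spec, 101)
  expect_identical(m1, m2)
  expect_false(identical(unclass_m(m1), unclass_m(generate_mask(spec, 102))))
  # every pixel center agrees with a direct point-in-region re-evaluation
  bnd <- attr(m1, "boundary")
  s <- spec$image_size
  xs <- (seq_len(s) - 0.5) / s
  oracle <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    dx <- xs[i] - bnd$cy; dy <- xs[j] - bnd$cx
    lim <- bnd$r0 * (1 + sum(bnd$a * cos(seq_along(bnd$a) *
                                           atan2(dy, dx) + bnd$phi)))
    oracle[i, j] <- as.numeric(sqrt(dx^2 + dy^2) <= lim)
  }
  expect_equal(unclass_m(m1), oracle)
})

test_that("a zero-amplitude boundary yields a disc of the predicted area", {
  spec <- synthetic_spec(image_size = 96L, boundary_amplitude = 0,
                        lesion_radius_range = c(0.25, 0.25), seed = 2L)
  m <- generate_mask(spec, 7)
  expect_lt(abs(mean(m) - pi * 0.25^2) / (pi * 0.25^2), 0.02)
})

test_that("masks are a single 4-connected component", {
  spec <- synthetic_spec(image_size = 40L, seed = 3L)
  for (sd in 1:5) {
    m <- generate_mask(spec, sd)
    # flood fill from one foreground pixel
    lab <- matrix(0L, nrow(m), ncol(m))
    start <- which(m == 1, arr.ind = TRUE)[1, ]
    queue <- list(start)
    lab[start[1], start[2]] <- 1L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (all(q >= 1) && q[1] <= nrow(m) && q[2] <= ncol(m) &&
            m[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- 1L
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    expect_equal(sum(lab), sum(m))
  }
})

test_that("rendering produces exactly two colors when all perturbations vanish", {
  spec <- synthetic_spec(image_size = 32L, color_jitter = 0,
                        illumination_gradient = 0, noise_sigma = 0, seed = 4L)
  m <- generate_mask(spec, 11)
  img <- render_image(m, spec, 12)
  for (c in 1:3) {
    vals <- unique(as.numeric(img[c, , ]))
    expect_lte(length(vals), 2)
  }
  expect_true(all(img >= 0 & img <= 1))
  # lesion darker than skin on every channel
  expect_true(all(vapply(1:3, function(c)
    mean(img[c, , ][m == 1]) < mean(img[c, , ][m == 0]), logical(1))))
})

test_that("rendered contrast matches the spec colors within noise tolerance", {
  spec <- synthetic_spec(image_size = 64L, color_jitter = 0,
                        illumination_gradient = 0, noise_sigma = 0.02,
                        seed = 5L)
  m <- generate_mask(spec, 21)
  img <- render_image(m, spec, 22)
  for (c in 1:3) {
    contrast <- mean(img[c, , ][m == 1]) - mean(img[c, , ][m == 0])
    want <- spec$lesion_color[c] - spec$skin_color[c]
    n <- min(sum(m == 1), sum(m == 0))
    expect_lt(abs(contrast - want), 3 * spec$noise_sigma / sqrt(n) + 1e-3)
  }
})

test_that("artifacts darken strokes, brighten bubbles, and leave the mask alone", {
  spec <- synthetic_spec(image_size = 32L, noise_sigma = 0, seed = 6L)
  m <- generate_mask(spec, 31)
  img <- render_image(m, spec, 32)
  same <- add_artifacts(img, spec, 33, hair_count = 0, bubble_count = 0)
  expect_equal(unclass_m(same), unclass_m(img))
  dec <- add_artifacts(img, spec, 33, hair_count = 3, bubble_count = 2)
  expect_equal(attr(dec, "provenance"), list(hairs = 3L, bubbles = 2L))
  # hairs only darken; bubbles only brighten; check a hair-only image
  hair_only <- add_artifacts(img, spec, 33, hair_count = 2, bubble_count = 0)
  expect_true(all(hair_only <= img + 1e-12))
  expect_gt(sum(hair_only < img - 1e-6), 0)
  bub_only <- add_artifacts(img, spec, 33, hair_count = 0, bubble_count = 1)
  expect_true(all(bub_only >= img - 1e-12))
})

test_that("dataset generation is reproducible and matches its manifest", {
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  spec <- synthetic_spec(image_size = 24L, seed = 7L)
  man1 <- generate_dataset(spec, 3, d1)
  man2 <- generate_dataset(spec, 3, d2)
  expect_length(list.files(d1, pattern = "png$"), 6)
  for (f in list.files(d1, pattern = "png$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_equal(man1$samples[[2]]$sample_seed, man2$samples[[2]]$sample_seed)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the foreground fraction over many seeds sits in the radius-implied band", {
  spec <- synthetic_spec(image_size = 32L, seed = 12L)
  fracs <- vapply(1:200, function(i)
    mean(generate_mask(spec, asNamespace("lmsaunet")$sample_seed_for(spec, i))),
    numeric(1))
  # radii are uniform on (0.15, 0.30) so the mean area is near
  # pi * E[r^2] = pi * (0.15^2 + 0.15*0.3 + 0.3^2)/3, inflated slightly by
  # the boundary harmonics; allow a generous band
  mid <- pi * (0.15^2 + 0.15 * 0.3 + 0.3^2) / 3
  expect_gt(mean(fracs), mid * 0.8)
  expect_lt(mean(fracs), mid * 1.3)
  expect_true(all(fracs > 0))
})
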