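#' Synthetic dermoscopy sample specification
#'
#' Parameters of the seeded generator of dermoscopy-like image/mask pairs:
#' a single star-convex lesion blob with a radial-Fourier-perturbed boundary
#' on a skin-toned background, darker lesion fill with per-sample color
#' jitter, a linear illumination gradient, Gaussian pixel noise, and optional
#' hair-stroke and bright-bubble artifacts. Every sample is fully determined
#' by `(spec, sample_seed)`.
#'
#' @param image_size square image side S in pixels.
#' @param lesion_radius_range base lesion radius as a fraction of S,
#'   `(lo, hi)` inside (0, 0.5).
#' @param boundary_harmonics number of radial Fourier terms perturbing the
#'   boundary.
#' @param boundary_amplitude total relative boundary perturbation; kept below
#'   1 so the radius stays positive and the blob one connected region.
#' @param lesion_color,skin_color mean RGB triples in `[0, 1]`.
#' @param color_jitter per-sample RGB jitter standard deviation.
#' @param illumination_gradient maximum relative brightness slope across the
#'   frame.
#' @param hair_count_range integer range of dark hair strokes.
#' @param hair_thickness stroke half-width in pixels.
#' @param hair_darkness multiplicative darkening strength in `[0, 1]`.
#' @param bubble_count_range integer range of bright bubble artifacts.
#' @param bubble_brightness additive brightening strength in `[0, 1]`.
#' @param noise_sigma Gaussian pixel noise standard deviation.
#' @param seed master seed from which per-sample seeds are derived.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_size = 64L,
                           lesion_radius_range = c(0.15, 0.30),
                           boundary_harmonics = 6L,
                           boundary_amplitude = 0.25,
                           lesion_color = c(0.42, 0.28, 0.22),
                           skin_color = c(0.80, 0.60, 0.52),
                           color_jitter = 0.04,
                           illumination_gradient = 0.15,
                           hair_count_range = c(0L, 4L),
                           hair_thickness = 1.0,
                           hair_darkness = 0.35,
                           bubble_count_range = c(0L, 2L),
                           bubble_brightness = 0.25,
                           noise_sigma = 0.02,
                           seed = 1L) {
  if (any(lesion_radius_range <= 0) || any(lesion_radius_range >= 0.5) ||
      diff(lesion_radius_range) < 0) {
    stop("lesion_radius_range must be an increasing pair inside (0, 0.5)",
         call. = FALSE)
  }
  if (boundary_amplitude < 0 || boundary_amplitude >= 1) {
    stop("boundary_amplitude must lie in [0, 1) so the radius stays positive",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# derive an independent, reproducible seed for sample `index`, stage `stage`
sample_seed_for <- function(spec, index, stage = 0L) {
  (as.numeric(spec$seed) * 1000003 + index * 7919 + stage * 104729) %% 2147483647
}

# radial boundary function of one lesion: r(theta) = r0 (1 + sum a_k cos(k theta + phi_k))
draw_boundary <- function(spec) {
  r0 <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
  kh <- spec$boundary_harmonics
  a <- rnorm(kh) / seq_len(kh)
  if (kh > 0 && sum(abs(a)) > 0) {
    a <- a * spec$boundary_amplitude / sum(abs(a)) * runif(1, 0.5, 1)
  }
  phi <- runif(kh, 0, 2 * pi)
  cx <- 0.5 + runif(1, -0.06, 0.06)
  cy <- 0.5 + runif(1, -0.06, 0.06)
  list(r0 = r0, a = a, phi = phi, cx = cx, cy = cy)
}

lesion_radius <- function(bnd, theta) {
  r <- rep(1, length(theta))
  for (k in seq_along(bnd$a)) {
    r <- r + bnd$a[k] * cos(k * theta + bnd$phi[k])
  }
  bnd$r0 * r
}

#' Generate a lesion mask
#'
#' Rasterizes one star-convex region: pixel centers whose distance to the
#' lesion center is at most the radial boundary function at their angle are
#' foreground. Deterministic for a given `(spec, sample_seed)`.
#'
#' @param spec a [synthetic_spec()].
#' @param sample_seed integer seed for this sample.
#' @return An `S x S` binary matrix (single 4-connected component).
#' @export
generate_mask <- function(spec, sample_seed) {
  set.seed(as.integer(sample_seed %% 2147483647))
  s <- spec$image_size
  bnd <- draw_boundary(spec)
  xs <- (seq_len(s) - 0.5) / s
  dx <- outer(xs - bnd$cy, rep(1, s))          # rows = y axis of the raster
  dy <- outer(rep(1, s), xs - bnd$cx)
  theta <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)
  mask <- (rad <= lesion_radius(bnd, theta)) * 1
  attr(mask, "boundary") <- bnd
  mask
}

#' Render the photometric image for a mask
#'
#' Skin background and lesion fill (means jittered per sample), multiplied by
#' a linear illumination field and perturbed by Gaussian noise; values are
#' clipped to `[0, 1]`.
#'
#' @param mask an `S x S` binary matrix from [generate_mask()].
#' @param spec a [synthetic_spec()].
#' @param sample_seed integer seed for this sample's photometry.
#' @return A `3 x S x S` image array in `[0, 1]`.
#' @export
render_image <- function(mask, spec, sample_seed) {
  set.seed(as.integer(sample_seed %% 2147483647))
  s <- spec$image_size
  skin <- pmin(pmax(spec$skin_color + rnorm(3, sd = spec$color_jitter), 0), 1)
  lesion <- pmin(pmax(spec$lesion_color + rnorm(3, sd = spec$color_jitter), 0), 1)
  gx <- runif(1, -1, 1) * spec$illumination_gradient
  gy <- runif(1, -1, 1) * spec$illumination_gradient
  xs <- (seq_len(s) - 0.5) / s - 0.5
  illum <- 1 + outer(xs * gy, rep(1, s)) + outer(rep(1, s), xs * gx)
  img <- array(0, c(3L, s, s))
  for (c in 1:3) {
    plane <- (skin[c] + mask * (lesion[c] - skin[c])) * illum
    if (spec$noise_sigma > 0) {
      plane <- plane + rnorm(s * s, sd = spec$noise_sigma)
    }
    img[c, , ] <- plane
  }
  pmin(pmax(img, 0), 1)
}

# rasterize a soft stroke along a quadratic Bezier curve into an S x S
# coverage field in [0, 1]
stroke_field <- function(s, p0, p1, p2, half_width) {
  ts <- seq(0, 1, length.out = 4L * s)
  pts <- cbind((1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1],
               (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2])
  field <- matrix(0, s, s)
  win <- ceiling(half_width + 1.5)
  for (q in seq_len(nrow(pts))) {
    i0 <- max(1L, floor(pts[q, 1] - win)); i1 <- min(s, ceiling(pts[q, 1] + win))
    j0 <- max(1L, floor(pts[q, 2] - win)); j1 <- min(s, ceiling(pts[q, 2] + win))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - pts[q, 1])^2, (jj - pts[q, 2])^2, "+")
    w <- exp(-d2 / (2 * half_width^2))
    field[ii, jj] <- pmax(field[ii, jj], w)
  }
  field
}

#' Add hair and bubble artifacts
#'
#' Draws dark anti-aliased curved strokes (quadratic curves spanning the
#' frame) and bright soft-edged circles over a rendered image; the mask is
#' untouched, which is exactly the robustness property the artifacts exist to
#' probe. Counts are drawn from the spec ranges and recorded in the
#' `"provenance"` attribute.
#'
#' @param image a `3 x S x S` image.
#' @param spec a [synthetic_spec()].
#' @param sample_seed integer seed for this sample's artifacts.
#' @param hair_count,bubble_count optional fixed counts overriding the spec
#'   ranges.
#' @return The decorated image with a `provenance` attribute listing the
#'   primitive counts.
#' @export
add_artifacts <- function(image, spec, sample_seed, hair_count = NULL,
                          bubble_count = NULL) {
  set.seed(as.integer(sample_seed %% 2147483647))
  s <- spec$image_size
  pick <- function(rng) {                 # sample() misreads length-1 vectors
    vals <- rng[1]:rng[2]
    if (length(vals) == 1L) vals else sample(vals, 1)
  }
  n_hair <- if (is.null(hair_count)) pick(spec$hair_count_range)
            else as.integer(hair_count)
  n_bub <- if (is.null(bubble_count)) pick(spec$bubble_count_range)
           else as.integer(bubble_count)
  out <- image
  if (n_hair > 0) {
    for (k in seq_len(n_hair)) {
      p0 <- runif(2, 1, s); p2 <- runif(2, 1, s)
      p1 <- (p0 + p2) / 2 + runif(2, -s / 3, s / 3)
      f <- stroke_field(s, p0, p1, p2, spec$hair_thickness)
      shade <- 1 - spec$hair_darkness * f
      for (c in 1:3) out[c, , ] <- out[c, , ] * shade
    }
  }
  if (n_bub > 0) {
    xs <- seq_len(s)
    for (k in seq_len(n_bub)) {
      cx <- runif(1, 1, s); cy <- runif(1, 1, s)
      r <- runif(1, max(2, s / 32), s / 8)
      d2 <- outer((xs - cy)^2, (xs - cx)^2, "+")
      w <- exp(-(d2 / r^2)^2)
      for (c in 1:3) out[c, , ] <- out[c, , ] + spec$bubble_brightness * w *
          (1 - out[c, , ])
    }
  }
  out <- pmin(pmax(out, 0), 1)
  attr(out, "provenance") <- list(hairs = n_hair, bubbles = n_bub)
  out
}

#' Generate labeled samples in memory
#'
#' @param spec a [synthetic_spec()].
#' @param n number of samples.
#' @return A tibble with columns `stem`, `image` (list of `3 x S x S`
#'   arrays), `mask` (list of `S x S` binary matrices), `sample_seed`,
#'   `hairs`, `bubbles`.
#' @export
generate_samples <- function(spec, n) {
  rows <- lapply(seq_len(n), function(i) {
    sd_mask <- sample_seed_for(spec, i, 0L)
    sd_render <- sample_seed_for(spec, i, 1L)
    sd_art <- sample_seed_for(spec, i, 2L)
    mask <- generate_mask(spec, sd_mask)
    img <- add_artifacts(render_image(mask, spec, sd_render), spec, sd_art)
    tibble::tibble(stem = sprintf("img_%04d", i),
                   image = list(unclass_attr(img)),
                   mask = list(unclass_attr(mask)),
                   sample_seed = sd_mask,
                   hairs = attr(img, "provenance")$hairs,
                   bubbles = attr(img, "provenance")$bubbles)
  })
  dplyr::bind_rows(rows)
}

unclass_attr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Write a synthetic dataset to disk
#'
#' Emits `img_%04d.png` / `img_%04d_segmentation.png` pairs (the loader's
#' naming convention; masks are single-channel with foreground 255) plus a
#' JSON manifest holding the spec and per-sample seeds so any file can be
#' regenerated bit-identically.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of samples.
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly, as written to `manifest.json`.
#' @export
generate_dataset <- function(spec, n, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  samples <- generate_samples(spec, n)
  for (i in seq_len(n)) {
    img <- aperm(samples$image[[i]], c(2, 3, 1))   # png wants H x W x C
    png::writePNG(img, file.path(out_dir, paste0(samples$stem[i], ".png")))
    png::writePNG(samples$mask[[i]],
                  file.path(out_dir, paste0(samples$stem[i],
                                            "_segmentation.png")))
  }
  manifest <- list(
    spec = unclass(spec),
    n = n,
    samples = lapply(seq_len(n), function(i)
      list(stem = samples$stem[i], sample_seed = samples$sample_seed[i],
           hairs = samples$hairs[i], bubbles = samples$bubbles[i]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
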