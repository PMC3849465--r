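# Synthetic H&E-like fixtures: seeded generator of two-class histology
# images (high-entropy basophilic carcinoma-like blobs on a low-entropy
# eosinophilic stroma-like background) with ground-truth masks, standing in
# for non-deposited clinical fields so every stage is testable offline.

#' Specification of a synthetic histology fixture
#'
#' Magnification presets sweep blob and nucleus scales to emulate x4-x40
#' fields digitised at a fixed sensor resolution: lower magnification means
#' more, smaller lesion cross-sections and smaller apparent nuclei.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_roi_blobs number of carcinoma-like blobs.
#' @param blob_scale `c(min, max)` blob radius range in pixels.
#' @param nucleus_density nuclei per pixel^2 of blob area.
#' @param nucleus_radius `c(min, max)` nucleus semi-axis range in pixels.
#' @param roi_color basophilic base RGB triplet in `[0,1]`.
#' @param background_color eosinophilic base RGB triplet in `[0,1]`.
#' @param fiber_amplitude amplitude of the smooth stromal fiber texture.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param seed RNG seed; the whole fixture is a deterministic function of
#'   the spec including this seed.
#' @param preset one of `"mag4"`, `"mag10"`, `"mag20"`, `"mag40"`; presets
#'   override the blob/nucleus geometry arguments.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(image_size = c(256, 256),
                         n_roi_blobs = 2L,
                         blob_scale = c(40, 70),
                         nucleus_density = 0.02,
                         nucleus_radius = c(2, 4),
                         roi_color = c(0.62, 0.52, 0.74),
                         background_color = c(0.93, 0.78, 0.85),
                         fiber_amplitude = 0.03,
                         noise_sd = 0.02,
                         seed = 1L,
                         preset = NULL) {
  if (!is.null(preset)) {
    p <- switch(preset,
      mag4  = list(n_roi_blobs = 4L, blob_scale = c(16, 30),
                   nucleus_radius = c(1, 2), nucleus_density = 0.05),
      mag10 = list(n_roi_blobs = 2L, blob_scale = c(40, 70),
                   nucleus_radius = c(2, 4), nucleus_density = 0.02),
      mag20 = list(n_roi_blobs = 2L, blob_scale = c(60, 90),
                   nucleus_radius = c(3, 6), nucleus_density = 0.012),
      mag40 = list(n_roi_blobs = 1L, blob_scale = c(90, 115),
                   nucleus_radius = c(5, 9), nucleus_density = 0.006),
      stop("fixture_spec: unknown preset '", preset, "'"))
    n_roi_blobs <- p$n_roi_blobs; blob_scale <- p$blob_scale
    nucleus_radius <- p$nucleus_radius; nucleus_density <- p$nucleus_density
  }
  stopifnot(length(image_size) == 2, all(image_size >= 1),
            n_roi_blobs >= 0, length(blob_scale) == 2,
            all(roi_color >= 0 & roi_color <= 1),
            all(background_color >= 0 & background_color <= 1),
            nucleus_density >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_roi_blobs = as.integer(n_roi_blobs),
                 blob_scale = blob_scale,
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 roi_color = roi_color,
                 background_color = background_color,
                 fiber_amplitude = fiber_amplitude,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Smooth random field: coarse iid noise bilinearly upsampled and lightly
# blurred; amplitude in [-1, 1].
smooth_field <- function(h, w, coarse = 8L) {
  ch <- max(2L, ceiling(h / coarse)); cw <- max(2L, ceiling(w / coarse))
  z <- matrix(stats::runif(ch * cw, -1, 1), ch, cw)
  f <- resize_bilinear(z, h, w)
  conv_separable(f, binomial5())
}

# Rasterize one wobbly blob: center (cy, cx), base radius r0, boundary
# modulated by low-order harmonics.
blob_mask <- function(h, w, cy, cx, r0) {
  amp <- stats::runif(3, 0, 0.12)
  pha <- stats::runif(3, 0, 2 * pi)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + amp[1] * cos(2 * theta + pha[1]) +
                 amp[2] * cos(3 * theta + pha[2]) +
                 amp[3] * cos(4 * theta + pha[3]))
  (dy^2 + dx^2) <= rad^2
}

#' Generate one synthetic histology image with its ground-truth mask
#'
#' Background: smooth eosinophilic (pinkish) fibrous texture with low local
#' entropy. Inside the mask: basophilic (purple-blue) base densely seeded
#' with dark elliptical nuclei, giving high local entropy and strong
#' blue-yellow opponency. Additive Gaussian noise on all channels. The
#' output is a deterministic function of the spec.
#'
#' @param spec `fixture_spec`.
#' @return list with `image` (`rgb_image`) and `mask` (0/1 matrix).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    mask <- matrix(FALSE, h, w)
    if (spec$n_roi_blobs > 0L) {
      rmax <- spec$blob_scale[2]
      if (2 * spec$blob_scale[1] > min(h, w)) {
        stop("generate_image: blob radius range ",
             paste(spec$blob_scale, collapse = "-"),
             " px cannot fit a ", h, " x ", w, " image")
      }
      for (b in seq_len(spec$n_roi_blobs)) {
        r0 <- stats::runif(1, spec$blob_scale[1],
                           min(spec$blob_scale[2], min(h, w) / 2 - 1))
        margin <- min(r0, min(h, w) / 4)
        cy <- stats::runif(1, 1 + margin, h - margin)
        cx <- stats::runif(1, 1 + margin, w - margin)
        mask <- mask | blob_mask(h, w, cy, cx, r0)
      }
    }

    # stroma: pink base, gentle fiber texture (smooth, hence low entropy)
    bg <- spec$background_color
    fib1 <- smooth_field(h, w, coarse = 10L)
    fib2 <- smooth_field(h, w, coarse = 4L)
    r <- bg[1] + spec$fiber_amplitude * (0.6 * fib1 + 0.4 * fib2)
    g <- bg[2] + spec$fiber_amplitude * (1.2 * fib1 + 0.5 * fib2)
    b <- bg[3] + spec$fiber_amplitude * (0.8 * fib1 + 0.4 * fib2)

    # carcinoma-like tissue: purple base + chromatin mottle + dark nuclei
    if (any(mask)) {
      rc <- spec$roi_color
      mot <- smooth_field(h, w, coarse = 2L)
      roi_r <- rc[1] + 0.05 * mot
      roi_g <- rc[2] + 0.05 * mot
      roi_b <- rc[3] + 0.04 * mot
      n_nuc <- stats::rpois(1, spec$nucleus_density * sum(mask))
      if (n_nuc > 0) {
        inside <- which(mask)
        centers <- inside[sample.int(length(inside), min(n_nuc, length(inside)),
                                     replace = FALSE)]
        for (idx in centers) {
          ci <- (idx - 1L) %% h + 1L
          cj <- (idx - 1L) %/% h + 1L
          a <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
          ecc <- stats::runif(1, 0.55, 1)
          ang <- stats::runif(1, 0, pi)
          rr <- max(1L, ceiling(a))
          ri <- max(1L, ci - rr):min(h, ci + rr)
          cjj <- max(1L, cj - rr):min(w, cj + rr)
          dy <- matrix(ri - ci, length(ri), length(cjj))
          dx <- matrix(cjj - cj, length(ri), length(cjj), byrow = TRUE)
          u <- dx * cos(ang) + dy * sin(ang)
          v <- -dx * sin(ang) + dy * cos(ang)
          hit <- (u / a)^2 + (v / (a * ecc))^2 <= 1
          shade <- stats::runif(1, 0.75, 1)
          roi_r[ri, cjj][hit] <- 0.30 * shade
          roi_g[ri, cjj][hit] <- 0.22 * shade
          roi_b[ri, cjj][hit] <- 0.48 * shade
        }
      }
      r[mask] <- roi_r[mask]
      g[mask] <- roi_g[mask]
      b[mask] <- roi_b[mask]
    }

    if (spec$noise_sd > 0) {
      r <- r + stats::rnorm(h * w, 0, spec$noise_sd)
      g <- g + stats::rnorm(h * w, 0, spec$noise_sd)
      b <- b + stats::rnorm(h * w, 0, spec$noise_sd)
    }
    list(image = rgb_image(clamp01(r), clamp01(g), clamp01(b)),
         mask = matrix(as.integer(mask), h, w))
  })
}

# Seed schedules keeping training and test fixtures disjoint by construction.
train_seed <- function(base_seed, i) as.integer(base_seed + 700000L + i)
test_seed <- function(base_seed, i) as.integer(base_seed + i)

#' Generate a labeled training set of texton exemplars
#'
#' Emulates the exemplar-extraction protocol: `n_images` seeded fixtures
#' are generated (training seed range disjoint from the test range by
#' construction), `textons_per_class` patches are sampled from inside and
#' outside each ground-truth mask, and their (I, O, C, H) features are
#' computed against each image's own conspicuity context.
#'
#' @param spec `fixture_spec` template; per-image seeds are derived from
#'   `spec$seed`.
#' @param n_images number of training images (default 20).
#' @param textons_per_class patches per class per image.
#' @param params saliency parameters for the feature context.
#' @param entropy_bins histogram bins for the texton H feature.
#' @return list with `features` (matrix), `labels`, `manifest`
#'   (data.frame: image_id, row, col, label), `images`, `masks`.
#' @export
generate_training_set <- function(spec, n_images = 20L,
                                  textons_per_class = 10L,
                                  params = saliency_params(),
                                  entropy_bins = 32L) {
  stopifnot(inherits(spec, "fixture_spec"), n_images >= 1)
  feats <- list(); labs <- character(0); rows <- list()
  images <- list(); masks <- list()
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- train_seed(spec$seed, i)
    fx <- generate_image(sp)
    id <- sprintf("train_%03d", i)
    sal <- saliency_map(fx$image, params)
    ctx <- feature_context(sal, bins = entropy_bins)
    for (lab in c("roi", "background")) {
      tx <- extract_textons(fx$image, fx$mask, lab, n = textons_per_class,
                            seed = sp$seed + (lab == "roi"), image_id = id)
      for (t in tx) {
        feats[[length(feats) + 1L]] <- texton_features(t, ctx)
        labs <- c(labs, lab)
        rows[[length(rows) + 1L]] <-
          data.frame(image_id = id, row = t$row, col = t$col, label = lab)
      }
    }
    images[[id]] <- fx$image
    masks[[id]] <- fx$mask
  }
  list(features = do.call(rbind, feats),
       labels = labs,
       manifest = do.call(rbind, rows),
       images = images,
       masks = masks)
}

#' Build a texton database from synthetic training fixtures
#'
#' Convenience wrapper: [generate_training_set()] followed by
#' [build_database()].
#' @inheritParams generate_training_set
#' @return `texton_db`.
#' @export
build_training_db <- function(spec, n_images = 20L, textons_per_class = 10L,
                              params = saliency_params(),
                              entropy_bins = 32L) {
  ts <- generate_training_set(spec, n_images, textons_per_class,
                              params, entropy_bins)
  build_database(ts$features, ts$labels)
}
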