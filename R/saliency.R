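# Bottom-up saliency: center-surround feature maps for intensity, color
# opponency and Gabor orientation energy, promoted with the local-maxima
# normalization operator and combined into one [0,1] map.
#
# Pyramid levels are addressed 0-based throughout (level L lives at list
# index L + 1), matching the conventional scale notation c in {2,3,4},
# s = c + delta.

#' Default saliency-stage parameters
#'
#' Scale set and filter-bank settings of the classic architecture: centers
#' `c = 2,3,4`, surrounds `s = c + delta`, `delta = 3,4`, four Gabor angles,
#' feature maps combined at working scale 4 (1/16 resolution).
#'
#' @param c_levels center pyramid levels (0-based).
#' @param deltas surround offsets.
#' @param n_levels pyramid depth.
#' @param working_scale pyramid level at which maps are summed.
#' @param angles Gabor angles in degrees; the angle names the *edge*
#'   orientation the filter responds to most.
#' @param channel_weights weights for the (intensity, color, orientation)
#'   conspicuity channels in the final combination.
#' @return named list of parameters.
#' @export
saliency_params <- function(c_levels = 2:4, deltas = 3:4, n_levels = 9L,
                            working_scale = 4L,
                            angles = c(0, 45, 90, 135),
                            channel_weights = c(1, 1, 1) / 3) {
  list(c_levels = as.integer(c_levels), deltas = as.integer(deltas),
       n_levels = as.integer(n_levels),
       working_scale = as.integer(working_scale),
       angles = angles, channel_weights = channel_weights)
}

#' Across-scale center-surround difference
#'
#' Absolute difference between a fine ("center") pyramid level and a coarse
#' ("surround") level bilinearly upsampled to the center's resolution.
#'
#' @param pyr `pyramid`.
#' @param c,s 0-based center and surround levels, `s > c`.
#' @return non-negative matrix at level-`c` resolution.
#' @export
center_surround <- function(pyr, c, s) {
  stopifnot(inherits(pyr, "pyramid"))
  if (s <= c) stop("center_surround: require s > c (got c=", c, ", s=", s, ")")
  if (c + 1 > length(pyr) || s + 1 > length(pyr)) {
    stop("center_surround: pyramid has ", length(pyr),
         " levels; levels c=", c, ", s=", s, " not available")
  }
  fine <- pyr[[c + 1L]]
  coarse <- pyr[[s + 1L]]
  abs(fine - resize_bilinear(coarse, nrow(fine), ncol(fine)))
}

#' Quadrature Gabor kernel pair
#'
#' Even (cosine) and odd (sine) oriented band-pass kernels. `theta` names
#' the orientation of the edge/bar eliciting the strongest response (degrees
#' from the horizontal image axis); the carrier varies along the normal to
#' that direction. The even kernel is made exactly zero-mean by subtracting
#' an envelope-weighted constant; both kernels are L2-normalized.
#'
#' @param theta angle in degrees, one of 0, 45, 90, 135.
#' @param size odd kernel size in pixels.
#' @param sigma Gaussian envelope standard deviation (px).
#' @param lambda carrier wavelength (px).
#' @param gamma envelope aspect ratio (1 = isotropic).
#' @return list with matrices `even` and `odd`.
#' @export
gabor_kernel <- function(theta, size = 9L, sigma = 2.5, lambda = 5,
                         gamma = 1) {
  if (!theta %in% c(0, 45, 90, 135)) {
    stop("gabor_kernel: unsupported angle ", theta,
         " (supported: 0, 45, 90, 135)")
  }
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  d <- seq(-r, r)
  dx <- matrix(d, size, size, byrow = TRUE)   # column offset
  dy <- matrix(d, size, size)                  # row offset
  alpha <- (theta + 90) * pi / 180             # carrier normal to the edge
  xp <- dx * cos(alpha) + dy * sin(alpha)
  yp <- -dx * sin(alpha) + dy * cos(alpha)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xp / lambda)
  even <- even - env * sum(even) / sum(env)    # exact zero mean
  odd <- env * sin(2 * pi * xp / lambda)       # zero mean by antisymmetry
  list(even = even / sqrt(sum(even^2)),
       odd = odd / sqrt(sum(odd^2)))
}

# Orientation energy of one plane: quadrature magnitude of the Gabor pair.
gabor_energy <- function(p, theta, ...) {
  k <- gabor_kernel(theta, ...)
  e <- conv2_reflect(p, k$even)
  o <- conv2_reflect(p, k$odd)
  sqrt(e^2 + o^2)
}

#' Orientation-energy pyramid
#'
#' Applies the oriented band-pass quadrature pair at every level of the
#' intensity pyramid and returns the magnitude responses.
#'
#' @param intensity intensity plane (matrix) or a prebuilt `pyramid`.
#' @param theta angle in degrees (0, 45, 90, 135).
#' @param n_levels pyramid depth when `intensity` is a plane.
#' @return `pyramid` of non-negative energy planes.
#' @export
gabor_orientation_pyramid <- function(intensity, theta, n_levels = 9L) {
  pyr <- if (inherits(intensity, "pyramid")) intensity else
    gaussian_pyramid(intensity, n_levels)
  out <- lapply(pyr, gabor_energy, theta = theta)
  structure(out, class = "pyramid")
}

# Strict local-maximum values of a plane under 8-connectivity.
# Plateaus (connected components of equal value) count once; a plateau is a
# maximum only if every outside neighbor is strictly smaller.
local_max_values <- function(q) {
  h <- nrow(q); w <- ncol(q)
  if (h * w == 1L) return(q[1, 1])
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- q
  nbmax <- matrix(-Inf, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbmax <- pmax(nbmax, p[(2:(h + 1L)) + di, (2:(w + 1L)) + dj])
  }
  cand <- which(q >= nbmax)             # candidates: no strictly larger neighbor
  if (length(cand) == 0L) return(numeric(0))
  strictly <- q > nbmax
  vals <- numeric(0)
  # Fast path: isolated strict maxima need no plateau analysis.
  plateau <- cand[!strictly[cand]]
  vals <- c(vals, q[cand[strictly[cand]]])
  if (length(plateau) > 0L) {
    is_cand <- matrix(FALSE, h, w); is_cand[cand] <- TRUE
    seen <- matrix(FALSE, h, w)
    for (start in plateau) {
      if (seen[start]) next
      v <- q[start]
      queue <- start
      seen[start] <- TRUE
      comp <- integer(0)
      ok <- TRUE
      while (length(queue) > 0L) {
        cur <- queue[length(queue)]
        queue <- queue[-length(queue)]
        comp <- c(comp, cur)
        ci <- (cur - 1L) %% h + 1L
        cj <- (cur - 1L) %/% h + 1L
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ni <- ci + di; nj <- cj + dj
          if (ni < 1L || ni > h || nj < 1L || nj > w) next
          idx <- ni + (nj - 1L) * h
          if (q[idx] == v) {
            if (!is_cand[idx]) ok <- FALSE  # equal neighbor with a larger nb
            else if (!seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
          }
        }
      }
      if (ok) vals <- c(vals, v)
    }
  }
  vals
}

#' Map-promotion normalization operator
#'
#' Rescales a non-negative plane to `[0, 1]` (min-max) and multiplies it by
#' `(M - mbar)^2`, where `M = 1` is the global maximum after rescaling and
#' `mbar` is the mean of all *other* local maxima (strict 8-neighborhood
#' maxima, plateaus counted once, one instance of the global maximum
#' excluded). Maps with a single dominant peak are promoted; maps with many
#' comparable peaks are suppressed. Constant (including all-zero) input
#' returns an all-zero plane.
#'
#' @param p non-negative matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_map <- function(p) {
  stopifnot(is.matrix(p))
  if (min(p) < 0) stop("normalize_map: input must be non-negative")
  q <- rescale01(p)
  if (max(q) == 0) return(q)   # constant input (incl. all-zero): no structure
  vals <- local_max_values(q)
  # drop one instance of the global maximum (1 after rescale)
  drop1 <- match(max(vals), vals)
  others <- vals[-drop1]
  mbar <- if (length(others) == 0L) 0 else mean(others)
  q * (1 - mbar)^2
}

# Resize a feature map to the working-scale grid.
to_working <- function(m, wh, ww) {
  if (nrow(m) == wh && ncol(m) == ww) m else resize_bilinear(m, wh, ww)
}

# (c, s) level pairs available in a pyramid of `n` levels.
scale_pairs <- function(params, n_available) {
  pairs <- list()
  for (c in params$c_levels) for (d in params$deltas) {
    s <- c + d
    if (c + 1 <= n_available && s + 1 <= n_available) {
      pairs[[length(pairs) + 1L]] <- c(c = c, s = s)
    } else {
      message(sprintf(
        "conspicuity: dropping scale pair (c=%d, s=%d); pyramid has %d levels",
        c, s, n_available))
    }
  }
  if (length(pairs) == 0L) {
    stop("conspicuity: image too small for any center-surround scale pair")
  }
  pairs
}

#' Conspicuity maps for intensity, color and orientation
#'
#' Builds Gaussian pyramids for the intensity and the four color-opponent
#' planes, forms across-scale center-surround feature maps (double
#' opponency RG and BY for color; Gabor energy at four angles for
#' orientation), promotes each with [normalize_map()], sums at the working
#' scale, and promotes each channel sum once more.
#'
#' @param img `rgb_image`.
#' @param params see [saliency_params()].
#' @return list with matrices `I_bar`, `C_bar`, `O_bar` at working-scale
#'   resolution, plus `working_dim` and `full_dim`.
#' @export
conspicuity_maps <- function(img, params = saliency_params()) {
  stopifnot(inherits(img, "rgb_image"))
  intens <- to_intensity(img)
  pyrI <- suppressWarnings(gaussian_pyramid(intens, params$n_levels))
  nlev <- length(pyrI)
  wl <- min(params$working_scale, nlev - 1L)
  wh <- nrow(pyrI[[wl + 1L]]); ww <- ncol(pyrI[[wl + 1L]])
  pairs <- scale_pairs(params, nlev)

  sum_maps <- function(maps) Reduce(`+`, maps)

  # intensity channel
  imaps <- lapply(pairs, function(p)
    normalize_map(to_working(center_surround(pyrI, p["c"], p["s"]), wh, ww)))
  I_bar <- normalize_map(sum_maps(imaps))

  # color channel: double-opponent RG and BY differences across scales
  opp <- opponent_channels(img)
  pyrRG <- suppressWarnings(gaussian_pyramid(opp$R - opp$G, params$n_levels))
  pyrBY <- suppressWarnings(gaussian_pyramid(opp$B - opp$Y, params$n_levels))
  cmaps <- list()
  for (p in pairs) {
    cmaps[[length(cmaps) + 1L]] <- normalize_map(
      to_working(center_surround(pyrRG, p["c"], p["s"]), wh, ww))
    cmaps[[length(cmaps) + 1L]] <- normalize_map(
      to_working(center_surround(pyrBY, p["c"], p["s"]), wh, ww))
  }
  C_bar <- normalize_map(sum_maps(cmaps))

  # orientation channel: per-angle promoted sums, then summed across angles
  osum <- matrix(0, wh, ww)
  for (th in params$angles) {
    pyrO <- gabor_orientation_pyramid(pyrI, th)
    omaps <- lapply(pairs, function(p)
      normalize_map(to_working(center_surround(pyrO, p["c"], p["s"]), wh, ww)))
    osum <- osum + normalize_map(sum_maps(omaps))
  }
  O_bar <- normalize_map(osum)

  list(I_bar = I_bar, C_bar = C_bar, O_bar = O_bar,
       working_dim = c(wh, ww), full_dim = c(img$height, img$width))
}

#' Bottom-up saliency map
#'
#' Weighted mean of the promoted intensity, color and orientation
#' conspicuity maps, bilinearly upsampled to image resolution and min-max
#' rescaled to `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param img `rgb_image`.
#' @param params see [saliency_params()].
#' @return object of class `saliency_map`: `values` (matrix in `[0,1]` at
#'   image resolution), `conspicuity` (working-scale maps), `conspicuity_full`
#'   (the three maps upsampled to image resolution, for region/texton
#'   features), and `normalization` (the global max and mean-of-other-maxima
#'   record of the combined map).
#' @export
saliency_map <- function(img, params = saliency_params()) {
  cm <- conspicuity_maps(img, params)
  w <- params$channel_weights
  comb <- w[1] * normalize_map(cm$I_bar) +
          w[2] * normalize_map(cm$C_bar) +
          w[3] * normalize_map(cm$O_bar)
  vals <- local_max_values(comb)
  norm_rec <- list(max = if (length(vals)) max(vals) else max(comb),
                   mean_other_maxima =
                     if (length(vals) > 1) mean(vals[-match(max(vals), vals)])
                     else 0)
  full <- rescale01(resize_bilinear(comb, cm$full_dim[1], cm$full_dim[2]))
  structure(list(
    values = full,
    conspicuity = cm[c("I_bar", "C_bar", "O_bar")],
    conspicuity_full = list(
      I = resize_bilinear(cm$I_bar, cm$full_dim[1], cm$full_dim[2]),
      C = resize_bilinear(cm$C_bar, cm$full_dim[1], cm$full_dim[2]),
      O = resize_bilinear(cm$O_bar, cm$full_dim[1], cm$full_dim[2])),
    normalization = norm_rec
  ), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map %d x %d, max %.3f, mean %.3f>\n",
              nrow(x$values), ncol(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# Accept either a saliency_map or a bare matrix where a plane is expected.
as_plane <- function(x) {
  if (inherits(x, "saliency_map")) x$values
  else if (inherits(x, "entropy_map")) x$values
  else { stopifnot(is.matrix(x)); x }
}
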