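# Region stage: superpixel segmentation in (color, position) space, windowed
# Shannon-entropy "structural disorder" map, per-region feature summaries and
# entropy-regulated attention scores that fix the search order.

#' Superpixel segmentation by proximity and color similarity
#'
#' Deterministic SLIC-style clustering: cluster centers are seeded on a
#' regular grid, pixels are assigned by the combined distance
#' `sqrt(d_rgb^2 + (compactness * d_xy / S)^2)` (colors in `[0,1]`, `S` the
#' grid spacing), centers are re-estimated for a fixed number of iterations,
#' and spatial connectivity is enforced by merging small disconnected
#' fragments into their dominant neighbor. Labels are renumbered compactly
#' in raster order of first occurrence.
#'
#' @param img `rgb_image`.
#' @param target_n requested number of regions (approximate; the realised
#'   count depends on the seed grid and merging). Default 200, sized for
#'   1280 x 1024 fields.
#' @param compactness spatial regularisation weight in color units
#'   (default 0.2; larger = squarer regions).
#' @param iterations assignment/update sweeps.
#' @return object of class `region_map`: `labels` (integer matrix, ids
#'   `1..n_regions`, every id used) and `n_regions`.
#' @export
segment_regions <- function(img, target_n = 200L, compactness = 0.2,
                            iterations = 10L) {
  stopifnot(inherits(img, "rgb_image"))
  h <- img$height; w <- img$width
  npx <- h * w
  if (target_n < 1) stop("segment_regions: target_n must be >= 1")
  if (target_n > npx) {
    stop("segment_regions: target_n (", target_n,
         ") exceeds pixel count (", npx, ")")
  }
  if (target_n == 1L) {
    return(structure(list(labels = matrix(1L, h, w), n_regions = 1L),
                     class = "region_map"))
  }
  nx <- max(1L, round(sqrt(target_n * w / h)))
  ny <- max(1L, round(target_n / nx))
  S <- sqrt(npx / (nx * ny))
  cx <- (seq_len(nx) - 0.5) * w / nx
  cy <- (seq_len(ny) - 0.5) * h / ny
  centers <- cbind(
    y = rep(cy, times = nx), x = rep(cx, each = ny),
    r = 0, g = 0, b = 0)
  rowv <- matrix(seq_len(h), h, w)
  colv <- matrix(seq_len(w), h, w, byrow = TRUE)
  # initialise center colors from the seed pixel
  for (k in seq_len(nrow(centers))) {
    i <- max(1L, min(h, round(centers[k, "y"])))
    j <- max(1L, min(w, round(centers[k, "x"])))
    centers[k, 3:5] <- c(img$r[i, j], img$g[i, j], img$b[i, j])
  }
  m2 <- (compactness / S)^2
  label <- matrix(0L, h, w)
  for (it in seq_len(iterations)) {
    dist <- matrix(Inf, h, w)
    for (k in seq_len(nrow(centers))) {
      i0 <- max(1L, floor(centers[k, "y"] - 2 * S))
      i1 <- min(h, ceiling(centers[k, "y"] + 2 * S))
      j0 <- max(1L, floor(centers[k, "x"] - 2 * S))
      j1 <- min(w, ceiling(centers[k, "x"] + 2 * S))
      ri <- i0:i1; cj <- j0:j1
      d <- (img$r[ri, cj] - centers[k, "r"])^2 +
           (img$g[ri, cj] - centers[k, "g"])^2 +
           (img$b[ri, cj] - centers[k, "b"])^2 +
           m2 * ((rowv[ri, cj] - centers[k, "y"])^2 +
                 (colv[ri, cj] - centers[k, "x"])^2)
      upd <- d < dist[ri, cj]
      if (any(upd)) {
        dsub <- dist[ri, cj]; dsub[upd] <- d[upd]; dist[ri, cj] <- dsub
        lsub <- label[ri, cj]; lsub[upd] <- k; label[ri, cj] <- lsub
      }
    }
    # any pixel outside all windows (degenerate geometry): nearest center
    miss <- which(label == 0L)
    if (length(miss) > 0L) {
      for (idx in miss) {
        i <- (idx - 1L) %% h + 1L; j <- (idx - 1L) %/% h + 1L
        dd <- (img$r[idx] - centers[, "r"])^2 + (img$g[idx] - centers[, "g"])^2 +
          (img$b[idx] - centers[, "b"])^2 +
          m2 * ((i - centers[, "y"])^2 + (j - centers[, "x"])^2)
        label[idx] <- which.min(dd)
      }
    }
    if (it < iterations) {
      cnt <- tabulate(label, nbins = nrow(centers))
      sums <- rowsum(cbind(c(rowv), c(colv), c(img$r), c(img$g), c(img$b)),
                     group = c(label), reorder = TRUE)
      ks <- as.integer(rownames(sums))
      centers[ks, ] <- sums / cnt[ks]
    }
  }
  enforce_connectivity(label, min_size = max(4, floor(npx / (nx * ny) / 4)))
}

# Relabel connected components (4-connectivity) and merge fragments smaller
# than min_size into the neighboring component they touch most.
enforce_connectivity <- function(label, min_size) {
  h <- nrow(label); w <- ncol(label)
  comp <- connected_components(label)
  sizes <- tabulate(comp)
  repeat {
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0L) break
    merged_any <- FALSE
    # neighbor pairs (vertical and horizontal)
    for (s in small) {
      px <- which(comp == s)
      nb <- integer(0)
      for (idx in px) {
        i <- (idx - 1L) %% h + 1L; j <- (idx - 1L) %/% h + 1L
        if (i > 1L) nb <- c(nb, comp[idx - 1L])
        if (i < h) nb <- c(nb, comp[idx + 1L])
        if (j > 1L) nb <- c(nb, comp[idx - h])
        if (j < w) nb <- c(nb, comp[idx + h])
      }
      nb <- nb[nb != s]
      if (length(nb) == 0L) next   # whole image is one small component
      tb <- sort(table(nb), decreasing = TRUE)
      target <- as.integer(names(tb)[1])
      comp[px] <- target
      sizes[target] <- sizes[target] + sizes[s]
      sizes[s] <- 0L
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  # compact ids in raster order of first occurrence
  first <- !duplicated(c(comp))
  ids <- c(comp)[first]
  remap <- integer(max(comp))
  remap[ids] <- seq_along(ids)
  out <- matrix(remap[comp], h, w)
  structure(list(labels = out, n_regions = length(ids)),
            class = "region_map")
}

# 4-connected component labelling by iterative minimum-id propagation:
# every pixel repeatedly takes the smallest component id among itself and
# its same-label 4-neighbors until a fixpoint (monotone, so it terminates).
connected_components <- function(label) {
  h <- nrow(label); w <- ncol(label)
  comp <- matrix(seq_len(h * w), h, w)
  if (h > 1L) same_v <- label[-1, , drop = FALSE] == label[-h, , drop = FALSE]
  if (w > 1L) same_h <- label[, -1, drop = FALSE] == label[, -w, drop = FALSE]
  repeat {
    new <- comp
    if (h > 1L) {
      top <- new[-h, , drop = FALSE]; bot <- new[-1, , drop = FALSE]
      mn <- pmin(top, bot)
      top[same_v] <- mn[same_v]
      new[-h, ] <- top
      bot2 <- new[-1, , drop = FALSE]
      bot2[same_v] <- pmin(bot2, mn)[same_v]
      new[-1, ] <- bot2
    }
    if (w > 1L) {
      lf <- new[, -w, drop = FALSE]; rt <- new[, -1, drop = FALSE]
      mn <- pmin(lf, rt)
      lf[same_h] <- mn[same_h]
      new[, -w] <- lf
      rt2 <- new[, -1, drop = FALSE]
      rt2[same_h] <- pmin(rt2, mn)[same_h]
      new[, -1] <- rt2
    }
    if (identical(new, comp)) break
    comp <- new
  }
  matrix(match(comp, sort(unique(c(comp)))), h, w)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map %d x %d, %d regions>\n",
              nrow(x$labels), ncol(x$labels), x$n_regions))
  invisible(x)
}

#' Windowed Shannon-entropy map of structural disorder
#'
#' At every pixel, the Shannon entropy (bits) of the `bins`-level histogram
#' of intensity values in the window centered there; borders are handled by
#' symmetric reflection. Intensities are binned on equal-width intervals of
#' `[0, 1]`. Odd windows are centered; even windows are anchored half a
#' pixel up-left (an even window makes the exact 1-bit balanced two-tone
#' value attainable, which no odd window can realise).
#'
#' @param intensity matrix with values in `[0, 1]`.
#' @param window window side in pixels (>= 2; default 9).
#' @param bins number of histogram bins (>= 2; default 32).
#' @return object of class `entropy_map`: `values` (bits, in
#'   `[0, log2(bins)]`), `window`, `bins`.
#' @export
local_entropy_map <- function(intensity, window = 9L, bins = 32L) {
  stopifnot(is.matrix(intensity))
  if (window < 2) stop("local_entropy_map: window must be >= 2")
  if (bins < 2) stop("local_entropy_map: bins must be >= 2")
  h <- nrow(intensity); w <- ncol(intensity)
  if (window > h || window > w) {
    stop("local_entropy_map: window (", window,
         ") exceeds an image dimension (", h, " x ", w, ")")
  }
  before <- floor((window - 1) / 2)   # rows/cols above-left of the center
  after <- window - 1L - before
  q <- matrix(pmin(bins, floor(clamp01(intensity) * bins) + 1L), h, w)
  qp <- pad_reflect(q, top = before, bottom = after,
                    left = before, right = after)
  ph <- nrow(qp); pw <- ncol(qp)
  n <- window * window
  ent <- matrix(0, h, w)
  ri0 <- 1:(ph + 1L - window); ri1 <- (window + 1L):(ph + 1L)
  ci0 <- 1:(pw + 1L - window); ci1 <- (window + 1L):(pw + 1L)
  for (b in seq_len(bins)) {
    ind <- matrix(0, ph + 1L, pw + 1L)
    ind[-1, -1] <- qp == b
    sat <- apply(ind, 2, cumsum)       # cumulative down rows
    sat <- t(apply(sat, 1, cumsum))    # then across columns
    cnt <- sat[ri1, ci1] - sat[ri0, ci1] - sat[ri1, ci0] + sat[ri0, ci0]
    p <- cnt / n
    nz <- p > 0
    term <- matrix(0, h, w)
    term[nz] <- -p[nz] * log2(p[nz])
    ent <- ent + term
  }
  ent[ent < 0] <- 0
  structure(list(values = ent, window = as.integer(window),
                 bins = as.integer(bins)),
            class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf("<entropy_map %d x %d, window %d, %d bins, mean %.2f bits>\n",
              nrow(x$values), ncol(x$values), x$window, x$bins,
              mean(x$values)))
  invisible(x)
}

#' Per-region feature summaries
#'
#' Pours the pixel-level planes into the segmentation: for every region,
#' its area and the means of intensity (I), orientation-conspicuity energy
#' (O), color-conspicuity energy (C), local entropy (H, bits) and saliency.
#'
#' @param regions `region_map`.
#' @param saliency `saliency_map` or matrix at image resolution.
#' @param I_bar,C_bar,O_bar conspicuity planes at image resolution (e.g.
#'   `saliency_map()$conspicuity_full`). `I_bar` is accepted for interface
#'   symmetry but the summary intensity comes from `intensity`.
#' @param entropy `entropy_map` or matrix.
#' @param intensity intensity plane.
#' @return data.frame with columns `region_id`, `area`, `I`, `O`, `C`, `H`,
#'   `mean_saliency`.
#' @export
summarize_regions <- function(regions, saliency, I_bar, C_bar, O_bar,
                              entropy, intensity) {
  stopifnot(inherits(regions, "region_map"))
  sal <- as_plane(saliency); ent <- as_plane(entropy)
  dims <- dim(regions$labels)
  for (p in list(sal, C_bar, O_bar, ent, intensity)) {
    if (!all(dim(p) == dims)) {
      stop("summarize_regions: plane dimensions do not match the region map")
    }
  }
  g <- c(regions$labels)
  cnt <- tabulate(g, nbins = regions$n_regions)
  sums <- rowsum(cbind(I = c(intensity), O = c(O_bar), C = c(C_bar),
                       H = c(ent), mean_saliency = c(sal)),
                 group = g, reorder = TRUE)
  out <- data.frame(region_id = seq_len(regions$n_regions),
                    area = cnt,
                    sums / cnt)
  rownames(out) <- NULL
  out
}

#' Entropy-regulated attention scores and search order
#'
#' Multiplies each region's mean saliency by its normalized disorder
#' `H / log2(bins)` (texture knowledge regulating bottom-up saliency) and
#' orders regions for the target search: decreasing attention, ties broken
#' by larger area, then by lower region id.
#'
#' @param summaries data.frame from [summarize_regions()].
#' @param bins histogram bin count used for the entropy map (normalizes H).
#' @param form regulation form: `"multiplicative"` (default;
#'   `saliency x Hn`), `"additive"` (`(saliency + Hn)/2`) or `"exponent"`
#'   (`saliency x Hn^gamma`), where `Hn = H / log2(bins)`.
#' @param gamma exponent for `form = "exponent"`.
#' @return the summaries with an `attention` column, sorted in search order.
#' @export
attention_scores <- function(summaries, bins = 32L,
                             form = c("multiplicative", "additive",
                                      "exponent"),
                             gamma = 1) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  form <- match.arg(form)
  s <- summaries
  hn <- s$H / log2(bins)
  s$attention <- switch(form,
    multiplicative = s$mean_saliency * hn,
    additive = (s$mean_saliency + hn) / 2,
    exponent = s$mean_saliency * hn^gamma)
  s[order(-s$attention, -s$area, s$region_id), , drop = FALSE]
}
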