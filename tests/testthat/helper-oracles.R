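# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive re-derivations (loops, exhaustive scans) kept separate
# from the package's vectorised implementations.

rand_plane <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

rand_image <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(matrix(runif(h * w), h, w),
            matrix(runif(h * w), h, w),
            matrix(runif(h * w), h, w))
}

flip_h <- function(m) m[, ncol(m):1, drop = FALSE]

flip_image_h <- function(img) rgb_image(flip_h(img$r), flip_h(img$g), flip_h(img$b))

# --- bilinear resize, re-derived with per-pixel loops ---------------------
oracle_bilinear <- function(m, oh, ow) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    si <- (i - 0.5) * h / oh + 0.5
    si <- min(max(si, 1), h)
    i0 <- min(floor(si), h); i1 <- min(i0 + 1, h); wi <- si - i0
    for (j in seq_len(ow)) {
      sj <- (j - 0.5) * w / ow + 0.5
      sj <- min(max(sj, 1), w)
      j0 <- min(floor(sj), w); j1 <- min(j0 + 1, w); wj <- sj - j0
      out[i, j] <- (1 - wi) * ((1 - wj) * m[i0, j0] + wj * m[i0, j1]) +
                   wi * ((1 - wj) * m[i1, j0] + wj * m[i1, j1])
    }
  }
  out
}

oracle_center_surround <- function(pyr, c, s) {
  fine <- pyr[[c + 1]]
  abs(fine - oracle_bilinear(pyr[[s + 1]], nrow(fine), ncol(fine)))
}

# --- normalization operator, exhaustive 8-neighbor scan -------------------
# Assumes no value ties (continuous random planes), so strict per-pixel
# maxima suffice.
oracle_normalize_map <- function(p) {
  lo <- min(p); hi <- max(p)
  if (hi - lo <= 0) return(matrix(0, nrow(p), ncol(p)))
  q <- (p - lo) / (hi - lo)
  h <- nrow(q); w <- ncol(q)
  vals <- numeric(0)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    is_max <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && q[ni, nj] >= q[i, j]) {
        is_max <- FALSE
      }
    }
    if (is_max) vals <- c(vals, q[i, j])
  }
  others <- vals[-match(max(vals), vals)]
  mbar <- if (length(others) == 0) 0 else mean(others)
  q * (1 - mbar)^2
}

# --- conspicuity recomposition from the unit-tested primitives ------------
oracle_conspicuity <- function(img, params = saliency_params()) {
  intens <- to_intensity(img)
  pyrI <- suppressWarnings(gaussian_pyramid(intens, params$n_levels))
  nlev <- length(pyrI)
  wl <- min(params$working_scale, nlev - 1)
  wh <- nrow(pyrI[[wl + 1]]); ww <- ncol(pyrI[[wl + 1]])
  pairs <- list()
  for (c in params$c_levels) for (d in params$deltas) {
    if (c + d + 1 <= nlev) pairs <- c(pairs, list(c(c, c + d)))
  }
  rs <- function(m) if (all(dim(m) == c(wh, ww))) m else resize_bilinear(m, wh, ww)
  acc <- function(maps) Reduce(`+`, maps)
  I_bar <- normalize_map(acc(lapply(pairs, function(p)
    normalize_map(rs(center_surround(pyrI, p[1], p[2]))))))
  opp <- opponent_channels(img)
  pyrRG <- suppressWarnings(gaussian_pyramid(opp$R - opp$G, params$n_levels))
  pyrBY <- suppressWarnings(gaussian_pyramid(opp$B - opp$Y, params$n_levels))
  cm <- list()
  for (p in pairs) {
    cm <- c(cm, list(normalize_map(rs(center_surround(pyrRG, p[1], p[2])))),
            list(normalize_map(rs(center_surround(pyrBY, p[1], p[2])))))
  }
  C_bar <- normalize_map(acc(cm))
  osum <- matrix(0, wh, ww)
  for (th in params$angles) {
    pyrO <- gabor_orientation_pyramid(pyrI, th)
    osum <- osum + normalize_map(acc(lapply(pairs, function(p)
      normalize_map(rs(center_surround(pyrO, p[1], p[2]))))))
  }
  list(I_bar = I_bar, C_bar = C_bar, O_bar = normalize_map(osum))
}

# --- sliding-window entropy, per-pixel histogram loops --------------------
oracle_entropy <- function(intensity, window, bins) {
  h <- nrow(intensity); w <- ncol(intensity)
  refl <- function(i, n) {
    per <- 2 * n
    j <- ((i - 1) %% per + per) %% per
    ifelse(j < n, j + 1, per - j)
  }
  before <- floor((window - 1) / 2)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- refl(seq(i - before, i - before + window - 1), h)
    ci <- refl(seq(j - before, j - before + window - 1), w)
    v <- c(intensity[ri, ci])
    q <- pmin(bins, floor(pmin(pmax(v, 0), 1) * bins) + 1)
    p <- tabulate(q, nbins = bins) / length(q)
    p <- p[p > 0]
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# --- kNN neighbor sets, exhaustive all-pairs sort -------------------------
oracle_knn_neighbors <- function(features, probe, k,
                                 drop_dims = integer(0)) {
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  use <- setdiff(which(sdv > 0), drop_dims)
  z <- sweep(sweep(features, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
  zp <- (probe - mu) / ifelse(sdv > 0, sdv, 1)
  d <- apply(z[, use, drop = FALSE], 1,
             function(r) sqrt(sum((r - zp[use])^2)))
  ord <- sort.int(d, index.return = TRUE, method = "radix")$ix
  ord[seq_len(k)]
}

oracle_df <- function(a, b, scales, features = c("I", "O", "C", "H")) {
  tot <- 0
  for (f in features) tot <- tot + ((a[[f]] - b[[f]]) / scales[[f]])^2
  sqrt(tot)
}

# Shared small training database for pipeline-level unit tests (built once
# per test run; deliberately small for speed).
unit_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      sp <- fixture_spec(image_size = c(128, 128), n_roi_blobs = 1L,
                         blob_scale = c(35, 45), seed = 11)
      db <<- suppressMessages(
        build_training_db(sp, n_images = 3, textons_per_class = 8))
    }
    db
  }
})

# The frozen mag10 evaluation suite: a texton database from 20 training
# fixtures (10 textons/class each) and the pipeline configuration sized for
# 256x256 fields. Built once per test run and shared between the pipeline
# unit tests and the acceptance suite.
SUITE_SEED <- 7L

suite_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      sp <- fixture_spec(preset = "mag10", seed = SUITE_SEED)
      db <<- suppressMessages(
        build_training_db(sp, n_images = 20, textons_per_class = 10))
    }
    db
  }
})

suite_config <- function(...) {
  pipeline_config(target_n = 24, seed = SUITE_SEED, ...)
}
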