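# Internal numerical helpers shared across the pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# pmax(0, m) drops dim attributes when the first argument is scalar;
# this keeps them.
rectify <- function(x) {
  x[x < 0] <- 0
  x
}

#' Run an expression with a temporary RNG seed
#'
#' Saves the current RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never perturbs the caller's
#' random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force initialisation so we have a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Edge-inclusive ("symmetric") reflection index for 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period  # 0-based, in [0, 2n)
  ifelse(j < n, j + 1L, period - j)
}

# Pad a matrix by symmetric reflection (edge pixels included in the mirror).
pad_reflect <- function(m, top, bottom = top, left = top, right = left) {
  h <- nrow(m); w <- ncol(m)
  ri <- reflect_index(seq.int(1L - top, h + bottom), h)
  ci <- reflect_index(seq.int(1L - left, w + right), w)
  m[ri, ci, drop = FALSE]
}

#' Bilinear resampling with pixel-center alignment
#'
#' Maps output pixel centers onto input pixel centers
#' (`src = (i - 0.5) * n_in / n_out + 0.5`), clamping at the borders. The
#' mapping is symmetric under horizontal and vertical flips, which the
#' saliency stage relies on for its flip-equivariance property.
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return numeric `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  h <- nrow(m); w <- ncol(m)
  axis_weights <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    i0 <- pmin(floor(src), n_in)
    i1 <- pmin(i0 + 1, n_in)
    list(i0 = as.integer(i0), i1 = as.integer(i1), w = src - i0)
  }
  r <- axis_weights(h, out_h)
  cc <- axis_weights(w, out_w)
  rows <- m[r$i0, , drop = FALSE] * (1 - r$w) + m[r$i1, , drop = FALSE] * r$w
  rows[, cc$i0, drop = FALSE] * rep(1 - cc$w, each = out_h) +
    rows[, cc$i1, drop = FALSE] * rep(cc$w, each = out_h)
}

# Separable convolution with a 1-D kernel applied along rows then columns,
# symmetric-reflection borders. Kernel length must be odd.
conv_separable <- function(m, k) {
  stopifnot(length(k) %% 2 == 1)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_reflect(m, top = r, bottom = r, left = r, right = r)
  out <- matrix(0, h, w + 2L * r)
  for (i in seq_along(k)) {
    out <- out + k[i] * p[seq.int(i, i + h - 1L), , drop = FALSE]
  }
  res <- matrix(0, h, w)
  for (j in seq_along(k)) {
    res <- res + k[j] * out[, seq.int(j, j + w - 1L), drop = FALSE]
  }
  res
}

# Full 2-D convolution (correlation) with an odd-sized kernel,
# symmetric-reflection borders, implemented by shift-and-add.
conv2_reflect <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_reflect(m, top = rh, bottom = rh, left = rw, right = rw)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kern[i, j] != 0) {
        out <- out + kern[i, j] *
          p[seq.int(i, i + h - 1L), seq.int(j, j + w - 1L), drop = FALSE]
      }
    }
  }
  out
}

# 2-x-2 block mean with ceiling dimensions (odd trailing row/col averages the
# remaining samples only). Flip-symmetric for even dimensions.
block_mean_2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  oh <- ceiling(h / 2); ow <- ceiling(w / 2)
  ri0 <- 2L * seq_len(oh) - 1L
  ri1 <- pmin(ri0 + 1L, h)
  ci0 <- 2L * seq_len(ow) - 1L
  ci1 <- pmin(ci0 + 1L, w)
  # a trailing odd row/col is paired with itself, so the divisor is always 2
  rows <- (m[ri0, , drop = FALSE] + m[ri1, , drop = FALSE]) / 2
  (rows[, ci0, drop = FALSE] + rows[, ci1, drop = FALSE]) / 2
}

# Min-max rescale of a matrix to [0,1]. Input whose range is at floating
# round-off scale (<= 1e-12 relative to its magnitude) counts as constant
# and maps to all zeros, so that 1-ulp smoothing noise on flat images is
# not amplified into a full-range map.
rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 1e-12 * max(1, abs(hi), abs(lo))) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - lo) / (hi - lo)
}
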