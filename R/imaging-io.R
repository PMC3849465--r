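# Raster I/O, color decomposition and Gaussian pyramids.
#
# Images are held as `rgb_image` objects: three [0,1] float planes on a
# common pixel grid. Masks are plain 0/1 integer matrices. Planes are plain
# numeric matrices (rows = image rows).

#' Construct an RGB image from three channel planes
#'
#' @param r,g,b numeric matrices of identical dimensions with finite values
#'   in `[0, 1]`.
#' @return An object of class `rgb_image` with fields `r`, `g`, `b`,
#'   `height`, `width`.
#' @export
rgb_image <- function(r, g, b) {
  stopifnot(is.matrix(r), is.matrix(g), is.matrix(b))
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b))) {
    stop("rgb_image: channel planes must share identical dimensions")
  }
  vals <- c(r, g, b)
  if (!all(is.finite(vals))) stop("rgb_image: non-finite channel values")
  if (min(vals) < 0 || max(vals) > 1) {
    stop("rgb_image: channel values must lie in [0, 1]")
  }
  structure(list(r = r, g = g, b = b,
                 height = nrow(r), width = ncol(r)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px, mean intensity %.3f>\n",
              x$height, x$width, mean((x$r + x$g + x$b) / 3)))
  invisible(x)
}

#' Convert a decoded raster array to an `rgb_image`
#'
#' Grayscale planes are replicated to three channels; an alpha channel, if
#' present, is dropped.
#' @param a numeric matrix or `h x w x k` array with values in `[0, 1]`.
#' @return `rgb_image`.
#' @export
as_rgb_image <- function(a) {
  if (is.matrix(a)) return(rgb_image(a, a, a))
  stopifnot(length(dim(a)) == 3)
  k <- dim(a)[3]
  if (k == 1L) return(rgb_image(a[, , 1], a[, , 1], a[, , 1]))
  if (k == 2L) return(rgb_image(a[, , 1], a[, , 1], a[, , 1]))  # gray+alpha
  rgb_image(a[, , 1], a[, , 2], a[, , 3])
}

decode_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = try(png::readPNG(path), silent = TRUE),
    jpg = ,
    jpeg = try(jpeg::readJPEG(path), silent = TRUE),
    tif = ,
    tiff = stop("cannot decode ", path,
                ": TIFF is not supported in this build (no TIFF codec ",
                "available); convert to PNG or JPEG"),
    stop("cannot decode ", path, ": unsupported format '.", ext, "'")
  )
  if (inherits(a, "try-error")) {
    stop("cannot decode ", path, ": corrupt or unreadable raster")
  }
  a
}

#' Read an RGB image from disk
#'
#' Decodes a PNG or JPEG raster (8- or 16-bit) and scales values to
#' `[0, 1]`. Grayscale sources are replicated to three channels.
#'
#' @param path file path.
#' @return `rgb_image`.
#' @export
read_image <- function(path) as_rgb_image(decode_raster(path))

#' Write an RGB image as a lossless PNG
#' @param img `rgb_image`.
#' @param path output path (`.png`).
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- array(0, c(img$height, img$width, 3))
  a[, , 1] <- img$r; a[, , 2] <- img$g; a[, , 3] <- img$b
  png::writePNG(a, path)
  invisible(path)
}

#' Read a binary mask from a raster file
#'
#' Any nonzero value in any channel maps to 1 (the any-channel-nonzero rule
#' for color-encoded masks).
#'
#' @param path file path of a PNG/JPEG raster.
#' @return integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  a <- decode_raster(path)
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  m <- apply(a != 0, c(1, 2), any)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Write a binary mask as a single-channel 0/255 PNG
#' @param mask 0/1 matrix.
#' @param path output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Intensity plane of an image
#'
#' Per-pixel arithmetic mean of the three channels, the intensity channel of
#' the classic bottom-up attention architecture.
#' @param img `rgb_image`.
#' @return numeric matrix in `[0, 1]`.
#' @export
to_intensity <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  (img$r + img$g + img$b) / 3
}

#' Broadly-tuned color-opponent channels
#'
#' The four half-rectified opponent planes of the classic attention model:
#' \deqn{R = r - (g+b)/2,\; G = g - (r+b)/2,\; B = b - (r+g)/2,}
#' \deqn{Y = (r+g)/2 - |r-g|/2 - b,} each clamped below at zero.
#'
#' @param img `rgb_image`.
#' @return list with planes `R`, `G`, `B`, `Y`, all non-negative.
#' @export
opponent_channels <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  r <- img$r; g <- img$g; b <- img$b
  list(
    R = rectify(r - (g + b) / 2),
    G = rectify(g - (r + b) / 2),
    B = rectify(b - (r + g) / 2),
    Y = rectify((r + g) / 2 - abs(r - g) / 2 - b)
  )
}

# 5-tap binomial low-pass kernel (Gaussian approximation); sums to 1 so
# pyramid smoothing conserves total mass under symmetric-reflection borders.
binomial5 <- function() c(1, 4, 6, 4, 1) / 16

#' Gaussian pyramid of a plane
#'
#' Level 0 is the input; each subsequent level is low-pass smoothed with a
#' separable 5-tap binomial kernel, then downsampled by factor 2 via 2x2
#' block means (ceiling dimensions). Construction stops early, with a
#' warning, once a level degenerates to a single pixel, since further levels
#' would be identical.
#'
#' @param p numeric matrix.
#' @param n_levels requested number of levels (level 0 counts), default 9.
#' @return object of class `pyramid`: list of planes, element `i` holding
#'   level `i - 1`.
#' @export
gaussian_pyramid <- function(p, n_levels = 9L) {
  stopifnot(is.matrix(p), n_levels >= 1)
  k <- binomial5()
  levels <- vector("list", n_levels)
  levels[[1]] <- p
  cur <- p
  built <- 1L
  while (built < n_levels) {
    if (nrow(cur) == 1L && ncol(cur) == 1L) {
      warning(sprintf(
        "gaussian_pyramid: truncated at %d of %d levels (level %d is 1x1)",
        built, n_levels, built - 1L))
      break
    }
    cur <- block_mean_2(conv_separable(cur, k))
    built <- built + 1L
    levels[[built]] <- cur
  }
  structure(levels[seq_len(built)], class = "pyramid")
}

#' @export
print.pyramid <- function(x, ...) {
  dims <- vapply(x, function(p) sprintf("%dx%d", nrow(p), ncol(p)), "")
  cat(sprintf("<pyramid, %d levels: %s>\n", length(x),
              paste(dims, collapse = " ")))
  invisible(x)
}
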